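agent,site,isotope,sigma_nca,cbe_tumour,cbe_normal,tn_ratio,in_default_report,source
BPA,brain,B-10,8.66e-14,3.8,1.3,5,TRUE,intravenous BPA in brain; in-vivo CBE 3.6-3.8 (tumour) and 0.9-1.3 (normal); tumour:normal 5:1-8:1
BSH,brain,B-10,8.66e-14,1.2,0.37,1.2,FALSE,BSH in brain; in-vivo CBE 1.2-2.3 (tumour) and 0.37-0.5 (normal); tumour:normal 1.2:1-3.5:1
BPA,liver,B-10,8.66e-14,9.94,4.25,2.8,TRUE,BPA in liver; tumour/normal CBE 9.94/4.25; tumour:normal 2.8:1
BSH,liver,B-10,8.66e-14,4.22,0.94,0.3,TRUE,BSH in liver; tumour/normal CBE 4.22/0.94; tumour:normal 0.3:1
Gd-cell,generic,Gd-157,9.27e-15,5,5,70,TRUE,multi-Auger emitter incorporated within the cell; recommended CBE 5; tumour:normal >= 70:1
Gd-DNA,generic,Gd-157,9.27e-15,20,20,70,TRUE,multi-Auger emitter incorporated within DNA; recommended CBE 20; tumour:normal >= 70:1
Gd-DNA-bound,generic,Gd-157,9.27e-15,10,10,70,TRUE,emitter electrostatically bound to nuclear DNA; recommended CBE 10; tumour:normal >= 70:1
Gd-MC-DNA,generic,Gd-157,9.27e-15,12.5,12.5,70,TRUE,Monte Carlo lineal-energy estimate for electrons localised inside a DNA cylinder; CBE 12.5; tumour:normal >= 70:1
Gd-MC-cell,generic,Gd-157,9.27e-15,1.5,1.5,70,TRUE,Monte Carlo lineal-energy estimate for electrons outside the DNA cylinder; CBE 1.5; tumour:normal >= 70:1
Gd-DOTA-TPP,generic,Gd-157,9.27e-15,40,40,70,FALSE,DOTA gadolinium triphenylphosphonium complex; photon-activation-derived CBE ~40; tumour:normal >= 70:1
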