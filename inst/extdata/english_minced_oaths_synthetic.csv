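original_orth,original_asjp,minced_orth,minced_asjp,source
damn,dam,darn,dan,example
damn,dam,dang,daN,example
damn,dam,drat,drat,example
hell,hel,heck,hek,example
fucking,fakiN,frigging,frigiN,example
fucking,fakiN,flipping,flipiN,example
shit,Sit,shoot,Sut,example
shit,Sit,sugar,Suga,example
god,god,gosh,goS,example
god,god,golly,goli,example
jesus,jizas,jeepers,jipaz,example
jesus,jizas,gee whiz,ji wiz,example
bloody,bladi,blooming,blumiN,example
bastard,bastad,basket,baskit,example
christ,kraist,crikey,kraiki,example
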