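dataset,n_training_images,filter_min,refine_min,tiles_per_image,review_min,n_validation_images,n_candidates,n_accepted,trad_s_per_image
JC77,500,61.02,60.17,1,6.20,50,501,276,79.68
PAP,500,23.88,22.20,9.77,2.35,50,308,54,118.52
SO242,500,19.42,25.53,1,16.70,50,1094,257,69.6
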