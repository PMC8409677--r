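taxon,exine_class
Asteraceae,echinate
Pyrus_Prunus,striate
Robinia,psilate
Tilia,reticulate
Brassica,reticulate
Salix,reticulate
Phacelia,micro_reticulate
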