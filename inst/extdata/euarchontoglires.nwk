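(((((((((human:0.0012,chimp:0.0012):0.0006,gorilla:0.0018):0.0021,orangutan:0.0036):0.0045,rhesus:0.0066):0.0075,marmoset:0.015):0.0075,tarsier:0.027):0.003,(mouse_lemur:0.021,bushbaby:0.024):0.0075):0.006,treeshrew:0.039):0.0045,((((mouse:0.015,rat:0.018):0.03,guinea_pig:0.039):0.0045,squirrel:0.03):0.006,(rabbit:0.021,pika:0.027):0.015):0.009);
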