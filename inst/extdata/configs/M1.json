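{"alpha":1,"beta":0,"gamma":1,"delta":0,"x1":1,"x2":1,"x3":1,"y1":1,"y2":1,"y3":1,"y4":1,"iic_w":0.25,"cii_w":0.3,"T":1,"N":30}
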