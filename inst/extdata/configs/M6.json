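{"alpha":1,"beta":0,"gamma":0,"delta":0,"x1":1,"x2":1,"x3":0,"y1":0,"y2":0,"y3":0,"y4":0,"iic_w":0.2,"cii_w":0,"T":1,"N":4}
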