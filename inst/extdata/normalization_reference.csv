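label,clip_ordinal,frame,channel,raw,normalized
falling,1,1,0_x_(Nose),0.379765,0.374411
falling,1,2,0_x_(Nose),0.362753,0.353146
falling,1,3,0_x_(Nose),0.362748,0.353140
falling,1,1,0_y_(Nose),0.553287,0.569179
falling,1,2,0_y_(Nose),0.185408,0.244493
falling,1,3,0_y_(Nose),0.185095,0.244216
falling,1,1,0_z_(Nose),0.208805,0.685071
falling,1,2,0_z_(Nose),-0.32835,0.346481
falling,1,3,0_z_(Nose),-0.30977,0.358191
standing,1,1,0_x_(Nose),0.494136,0.517380
standing,1,2,0_x_(Nose),0.490758,0.513157
standing,1,3,0_x_(Nose),0.488241,0.510012
standing,1,1,0_y_(Nose),0.256956,0.30764
standing,1,2,0_y_(Nose),0.246923,0.298785
standing,1,3,0_y_(Nose),0.242574,0.294947
standing,1,1,0_z_(Nose),-0.41847,0.289674
standing,1,2,0_z_(Nose),-0.40555,0.297817
standing,1,3,0_z_(Nose),-0.40686,0.296995
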