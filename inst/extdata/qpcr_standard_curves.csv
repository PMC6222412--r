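label,quantity_ng,ct
C. militaris,15,7.55
C. militaris,1.5,10.30
C. militaris,0.15,13.65
C. militaris,0.015,17.27
C. militaris,0.0015,20.75
C. pruinosa,15,11.27
C. pruinosa,1.5,14.02
C. pruinosa,0.15,17.60
C. pruinosa,0.015,21.28
C. pruinosa,0.0015,24.46
I. cicadae,15,14.72
I. cicadae,1.5,17.97
I. cicadae,0.15,21.47
I. cicadae,0.015,24.76
I. cicadae,0.0015,28.19
I. tenuipes,15,13.89
I. tenuipes,1.5,14.62
I. tenuipes,0.15,17.50
I. tenuipes,0.015,20.88
I. tenuipes,0.0015,24.55
O. sinensis,15,8.31
O. sinensis,1.5,11.66
O. sinensis,0.15,15.06
O. sinensis,0.015,18.68
O. sinensis,0.0015,21.98
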