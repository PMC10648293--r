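patient,sex,age,procedure
1,M,62,Lumbar Decompression and Fusion
2,M,74,Lumbar Decompression and Fusion
3,M,60,Lumbar Decompression and Fusion
4,F,52,Lumbar Decompression and Fusion
5,M,51,Lumbar Decompression and Fusion
6,M,50,Lumbar Decompression and Fusion
7,F,63,Lumbar Decompression and Fusion
8,F,66,Thoracic Decompression and Fusion
9,M,49,Lumbar Decompression and Fusion
10,M,61,Lumbar Extradural Tumor Excision and Fusion
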