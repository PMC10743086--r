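culture,drug,ic50
NCI-H460,cisplatin,5.705
NCI-H460,etoposide,4.809
NCI-H460,paclitaxel,0.3808
NCI-H460,docetaxel,0.5541
NCI-H460,gemcitabine,41.565
NCI-H460,vinorelbine,0.03656
NCI-H460,pemetrexed,>300
NCI-H460,carboplatin,>100
NCI-H460/R,cisplatin,5.334
NCI-H460/R,etoposide,7.922
NCI-H460/R,paclitaxel,>5
NCI-H460/R,docetaxel,0.7041
NCI-H460/R,gemcitabine,33.588
NCI-H460/R,vinorelbine,0.9902
NCI-H460/R,pemetrexed,>300
NCI-H460/R,carboplatin,>100
MRC-5,cisplatin,14.682
MRC-5,etoposide,>30
MRC-5,paclitaxel,>5
MRC-5,docetaxel,>5
MRC-5,gemcitabine,>100
MRC-5,vinorelbine,>1
MRC-5,pemetrexed,>300
MRC-5,carboplatin,>100
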