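text,reference_polarity,reference_subjectivity
"Again, my daughter with her crises. This is already once a month, isn't it dreadful to know that she can not be like the rest of her friends or brothers??",-1,1
"Happy day Cri Du Chat dear family!!!",1,1
"This article provides rehabilitation exercises for cerebellar ataxia think it may be interesting for patients with Wolfram.",0.5,0.5
"I will attach separate interviews. The next one is aimed at parents.",0,0
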