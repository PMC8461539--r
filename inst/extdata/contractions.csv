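pattern,replacement,anchor
&,and,literal
can't,cannot,word
won't,will not,word
shan't,shall not,word
ain't,is not,word
let's,let us,word
it's,it is,word
that's,that is,word
what's,what is,word
there's,there is,word
he's,he is,word
she's,she is,word
who's,who is,word
n't," not",suffix
'll," will",suffix
're," are",suffix
've," have",suffix
'm," am",suffix
'd," would",suffix
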