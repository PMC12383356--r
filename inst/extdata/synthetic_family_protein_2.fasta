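>seq1 synthetic protein homolog
SEGGWSYGSFLLSHGLKTQMGSEADADYDEYQVAHRQARNILNINPVDRRGNHHDNDNH
>seq2 synthetic protein homolog
SFVGQSDMGAGKAHFGSAAADYARLRMMLQNINPVARNNHDNY
>seq3 synthetic protein homolog
SFGGAQHDMKMESLIKLSHRCDTQMGSVAADDYQRAQARYIRDRLQNNNPVTRRGNHDNY
>seq4 synthetic protein homolog
RFAQIDMGAGSLLSHLLKTQMGYHAAMYTQQRQLRMMSQFECFARRGRHHDNY
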