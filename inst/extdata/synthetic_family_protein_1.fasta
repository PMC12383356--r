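>seq1 synthetic protein homolog
HFTHNHNNRVCTFKAMQSILVFLGVQEIIHCTKHHYNIVRAMNFKWPWTKRHICFQLRWPCNLH
>seq2 synthetic protein homolog
HFTNNFFKAMQSILGFGGFGKEIIHCTKNHNIVRAMSFKWPWTKRHWCFRWPCFLH
>seq3 synthetic protein homolog
HLTNNHNNRVTFIAMQSILHQEIIHCTKNHNIVRAMSFKWPWTKRHCFRWPCNLH
>seq4 synthetic protein homolog
HKTNNHNNRVTFKAMQSVMTGGEEIIDHCTKNHNIVRAMSFKWPLTKRHICFRWPCNLH
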