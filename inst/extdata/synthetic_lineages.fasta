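>CDP02
YIGFAVETRLIRNKPWQHCNIYFGHWTFVRATRGWSSVNGPPCFYCRWWWGPHAPRFFIH
YTVHTRECITSKLLISMLCSPMECTTPTFATNKEWMNGTEWPHSPEMCSEMRGSNPYM
>aBAK1
YIGFAVETRLIRCHPWQHCYSYFGHWTFVRATRGWSSVDMWPCFYCRVWWGPHAPRFFIH
YTVHTRECITSKLLIPMLCSPMECTTPTFATNKHWMNGTEWPHSPEMCSEMRGSNPYM
>aBAK2
YIGCAVETRLIRCHPWQWCYSYFGHWTFVRATFGWSSVDMWPCFYCRVNWGPHAFRFFIH
YTNHTRECITSELLIPTLCSPMECTTPTFATNKHPNNTTEWPHSWEMCSEMRGSNPYM
>CDP01
CNYCPLMFMFKAKINLYTCVTWPAIYGDELCNWWNATPRLSPGGDNLVAIVAEAYTSTMP
AMIGYWYPIPLIDEADMFCSQAAIWERRPFIQHHMWENKYHTPAGPEKERDDISHED
>aBAX1
CNYCPLMFMFKAKINLYTCVTWPAIYRDELCWWWYATPRLSPGGDNLVAIVAEAYTSTMP
AMIGYWYPIPLIDEADNFCSQIAIWERRPFIQHHMWEEKYHTTAGPEKERDRISHED
>aBAX2
CNYCPQMFMFKAKINLYTCVTWPADYRDELCWWWYATPRLSPGGDNMVAIVAEAYTSTMP
AMIGYTYPGPLIDEADNFCMQIAIWERRPFIQHHMKEEKYHTTAGPEKEQDRIWTED
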