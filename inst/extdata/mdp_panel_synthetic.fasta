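>MOTS-c source=human_UniProt_A0A0B4J2F0
MRWQEMGYIFYPRKLR
>Humanin source=human_UniProt_Q8IVG9
MAPRGFSCLLLLTSEIDLPVKRRA
>SHLP1 source=synthetic_surrogate
MGFFDIKTEGATNELVEAANDICL
>SHLP2 source=synthetic_surrogate
MSVLQHQSLGSEWFVDHLMRQATFKC
>SHLP3 source=synthetic_surrogate
MGFLPDTVMNGRSNWRMMVYFQMTRYSYTRPQVDESQI
>SHLP4 source=synthetic_surrogate
MVRAANSGYIEQEKPHRHIWKQTYVN
>SHLP5 source=synthetic_surrogate
MYMDFAIQWHFFIAWTTLWEFWMC
>SHLP6 source=synthetic_surrogate
MPLFYAVNQGNEQYSFLTKQ
>SHMOOSE source=synthetic_surrogate
MCFCHDVVRFYWPRINHIGFEKEMYNDIFSDNFFQYMVTYSTCFCCPDANIRSRHNWL
>MTALTND4 source=synthetic_surrogate
MYFWDAKRFNKCAPQTLAIHIWWTYRCDLQKIMIGTRSIANFCHVDMKRLVSLTFTQVSNWDFDRAKLACIDINCYKTQKRMFNEAKYRTLDNWIIYTD
>Gau source=synthetic_surrogate
MKLSSYKVSIKGIWRLDPFFVADADCFRNGAPKTIMFPDPIKQGTRYSRREFTMWCWSQACSVSNVRNLCNYPQWVRQVHEPRQGDSVNHTCEEQYQKSD
>CYTB-187AA source=synthetic_surrogate
MEYEKLTRFQDEKCPPWGSAGRICPGNKDPKWPINQIGVKENTFEGQSLVYQVASVNIPSINRHETCFAFLMENYEPPAGDDYTESIPPFPFSWETSQNTGGMMASCLYYCCTWKTKHVFPMKSKIMCAFDKFFREFCPFMADHPKQWVMATHWTMLHLTRVRVCNLQLYNHPRVTMLELDYGDFGW
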