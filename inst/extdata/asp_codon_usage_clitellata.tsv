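organism	GAC	GAT
Lumbricus terrestris	34	40
Perionyx excavatus	42	32
Tonoscolex birmanicus	41	28
Amynthas aspergillus	43	28
Metaphire vulgaris	32	40
Whitmania pigra	12	78
Haementeria officinalis	8	58
Placobdella parasitica	14	56
Placobdella lamothei	27	45
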