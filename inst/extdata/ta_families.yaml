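# Toxin and antitoxin family ids recognized inside cas loci, plus other
# known non-cas families routed to the assorted-functions report when found
# as intervening genes.
toxins: [Fic_DOC, PIN]
antitoxins: [PhdYeFM_antitox, Antitoxin-MazE, Unstab_antitox, TIGR02612]
other_known:
  - Transposase_20
  - Transposase_mut
  - DDE_Tnp_1
  - DUF2276
  - 23S_rRNA_IVP
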