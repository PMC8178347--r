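# Demo synthetic community: four bacteria-like members (one of mixed
# linked/unlinked architecture) and one archaea-like member whose genome
# lacks the 27F primer site, so it is invisible to full-length 16S
# amplicon sequencing but visible to operon amplicon and shotgun reads.
members:
  - species: Alphabacter primus
    taxid: 1001
    abundance: 0.30
    n_copies: 4
  - species: Betabacter secundus
    taxid: 1002
    abundance: 0.25
    n_copies: 4
  - species: Gammabacter tertius
    taxid: 1003
    abundance: 0.20
    n_copies: 3
  - species: Mixtobacter quartus
    taxid: 1004
    abundance: 0.15
    n_copies: 4
    linked_fraction: 0.5
  - species: Archaeoides quintus
    taxid: 2001
    abundance: 0.10
    n_copies: 2
    superkingdom: Archaea
    primer_absent: [27F]
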