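# Built-in gene catalog: curated case-control gene groups plus the rules
# needed to resolve any symbol to a solute-carrier (SLC) family number.
groups:
  A:  # detoxification / oxidative stress candidates
    - CAT
    - CCKBR
    - CYP2D6
    - FADS1
    - GSTM1
    - GSTP1
    - GSTT1
    - MTHFR
    - NAT2
    - NOS2
    - NOS3
    - OPRL1
    - PON1
    - PPARG
    - SCN9A
    - SIRT1
    - SOD2
  B:  # transient receptor potential (TRP) ion-channel family
    - TRPA1
    - TRPC1
    - TRPC2
    - TRPC3
    - TRPC4
    - TRPC5
    - TRPC6
    - TRPC7
    - TRPM1
    - TRPM2
    - TRPM3
    - TRPM4
    - TRPM5
    - TRPM6
    - TRPM7
    - TRPM8
    - MCOLN1
    - MCOLN2
    - MCOLN3
    - PKD1
    - PKD2
    - PKD2L1
    - PKD2L2
    - TRPV1
    - TRPV2
    - TRPV3
    - TRPV4
    - TRPV5
    - TRPV6
  D_risk:  # GWAS risk-SNP genes
    - ANKRD6
    - NALF1
    - WWOX
    - DAB1
    - RIMS2
    - DOCK2
    - SLC25A38
    - GIGYF2
    - BCAS3
    - STK32B
    - ECHDC2
  D_protective:  # GWAS protective-SNP genes
    - GRIN2A
    - GNA12
    - CXCR2P1
    - LRIG2
    - TNIK
    - PAK5
    - TSPAN9
    - ARHGAP22
# second names that resolve to the same catalog entry
symbol_synonyms:
  FAM155A: NALF1
  PAK7: PAK5
  SLC25A50: MTCH2
# atypically named SLC members: alias prefix -> family number.
# Matching is whole-prefix with a digit/letter boundary so that e.g. CAT or
# MFSD20 can never be caught by an alias.
slc_alias_prefixes:
  SLCO: 21
  UCP: 25
  MTCH: 25
  RHAG: 42
  RHBG: 42
  RHCG: 42
  FLVCR: 49
  XPR1: 53
  MPC: 54
  LETM: 55
  SFXN: 56
  NIPA: 57
  MAGT: 58
  MFSD2: 59
  MFSD3: 60
  MFSD4: 61
  MFSD5: 61
  ANKH: 62
  SPNS: 63
  NPC: 65
  CTNS: 66
  MPDU1: 66
# TMEM is a huge unrelated symbol space; only the explicit members below
# belong to SLC family 64 (Golgi Ca2+/H+ exchangers).
tmem_family64:
  - TMEM165
# SLC families tied to neurotransmitter synthesis, release and clearance
restricted_families: [1, 4, 5, 6, 7, 8, 10, 16, 17, 18, 22, 38]
# symbols on the X chromosome (drives hemizygous calls in males)
xlinked:
  - SLC6A14
  - SLC9A7
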