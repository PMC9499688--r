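# oligolens residue templates: idealized geometry (nm) + role annotations
# ATOM <name> <element> <MC|SC> <x> <y> <z>
RES GLY peptide
ATOM N N MC 0.00000 0.00000 0.00000
ATOM CA C MC 0.14580 0.00000 0.00000
ATOM C C MC 0.20095 0.14218 0.00000
ATOM O O MC 0.12465 0.23879 0.00000
ATOM H H MC -0.04897 -0.08834 -0.00000
ANCHOR N CA C
DONOR N H
ACCEPTOR O
RES ALA peptide
ATOM N N MC 0.00000 0.00000 0.00000
ATOM CA C MC 0.14580 0.00000 0.00000
ATOM C C MC 0.20095 0.14218 0.00000
ATOM O O MC 0.12465 0.23879 0.00000
ATOM H H MC -0.04897 -0.08834 -0.00000
ATOM CB C SC 0.19938 -0.07166 -0.12411
ANCHOR N CA C
DONOR N H
ACCEPTOR O
METHYL CB
RES SER peptide
ATOM N N MC 0.00000 0.00000 0.00000
ATOM CA C MC 0.14580 0.00000 0.00000
ATOM C C MC 0.20095 0.14218 0.00000
ATOM O O MC 0.12465 0.23879 0.00000
ATOM H H MC -0.04897 -0.08834 -0.00000
ATOM CB C SC 0.19938 -0.07166 -0.12411
ATOM OG O SC 0.34108 -0.07203 -0.12475
ATOM HG H SC 0.37106 -0.11763 -0.20373
ANCHOR N CA C
DONOR N H
DONOR OG HG
ACCEPTOR O
ACCEPTOR OG
RES ASN peptide
ATOM N N MC 0.00000 0.00000 0.00000
ATOM CA C MC 0.14580 0.00000 0.00000
ATOM C C MC 0.20095 0.14218 0.00000
ATOM O O MC 0.12465 0.23879 0.00000
ATOM H H MC -0.04897 -0.08834 -0.00000
ATOM CB C SC 0.19938 -0.07166 -0.12411
ATOM CG C SC 0.35088 -0.07443 -0.12892
ATOM OD1 O SC 0.41774 -0.02275 -0.03941
ATOM ND2 N SC 0.40553 -0.13495 -0.23374
ATOM HD21 H SC 0.50603 -0.13997 -0.24243
ATOM HD22 H SC 0.34659 -0.17596 -0.30477
ANCHOR N CA C
DONOR N H
DONOR ND2 HD21
DONOR ND2 HD22
ACCEPTOR O
ACCEPTOR OD1
RES PHE peptide
ATOM N N MC 0.00000 0.00000 0.00000
ATOM CA C MC 0.14580 0.00000 0.00000
ATOM C C MC 0.20095 0.14218 0.00000
ATOM O O MC 0.12465 0.23879 0.00000
ATOM H H MC -0.04897 -0.08834 -0.00000
ATOM CB C SC 0.19938 -0.07166 -0.12411
ATOM CG C SC 0.34963 -0.07599 -0.13161
ATOM CD1 C SC 0.41902 0.02626 -0.19527
ATOM CD2 C SC 0.41902 -0.18224 -0.07489
ATOM CE1 C SC 0.55779 0.02226 -0.20220
ATOM CE2 C SC 0.55779 -0.18624 -0.08182
ATOM CZ C SC 0.62717 -0.08399 -0.14547
ANCHOR N CA C
DONOR N H
ACCEPTOR O
RING CG,CD1,CE1,CZ,CE2,CD2
RES ILE peptide
ATOM N N MC 0.00000 0.00000 0.00000
ATOM CA C MC 0.14580 0.00000 0.00000
ATOM C C MC 0.20095 0.14218 0.00000
ATOM O O MC 0.12465 0.23879 0.00000
ATOM H H MC -0.04897 -0.08834 -0.00000
ATOM CB C SC 0.19938 -0.07166 -0.12411
ATOM CG1 C SC 0.15090 -0.21674 -0.12702
ATOM CG2 C SC 0.35148 -0.07166 -0.12411
ATOM CD1 C SC 0.19959 -0.29499 -0.24701
ANCHOR N CA C
DONOR N H
ACCEPTOR O
METHYL CG2
METHYL CD1
RES LEU peptide
ATOM N N MC 0.00000 0.00000 0.00000
ATOM CA C MC 0.14580 0.00000 0.00000
ATOM C C MC 0.20095 0.14218 0.00000
ATOM O O MC 0.12465 0.23879 0.00000
ATOM H H MC -0.04897 -0.08834 -0.00000
ATOM CB C SC 0.19938 -0.07166 -0.12411
ATOM CG C SC 0.15888 -0.21828 -0.14051
ATOM CD1 C SC 0.21885 -0.27675 -0.26748
ATOM CD2 C SC 0.00760 -0.23167 -0.14884
ANCHOR N CA C
DONOR N H
ACCEPTOR O
METHYL CD1
METHYL CD2
RES ACE cap
ATOM CH3 C MC 0.00000 0.00000 0.00000
ATOM C C MC 0.15200 0.00000 0.00000
ATOM O O MC 0.21448 0.10607 0.00000
ANCHOR CH3 C O
ACCEPTOR O
RES NH2 cap
ATOM N N MC 0.00000 0.00000 0.00000
ATOM HN1 H MC 0.10100 0.00000 0.00000
ATOM HN2 H MC -0.05050 0.08747 0.00000
ANCHOR N HN1 HN2
DONOR N HN1
DONOR N HN2
RES MEL ligand
ATOM N1 N SC 0.13267 -0.04311 0.00000
ATOM C2 C SC 0.21467 0.06975 0.00000
ATOM C3 C SC 0.13267 0.18261 0.00000
ATOM C3A C SC 0.00001 0.13950 0.00000
ATOM C4 C SC -0.12080 0.20925 0.00000
ATOM C5 C SC -0.24161 0.13950 0.00000
ATOM C6 C SC -0.24161 -0.00000 0.00000
ATOM C7 C SC -0.12080 -0.06975 0.00000
ATOM C7A C SC 0.00001 0.00000 0.00000
ATOM HN1 H SC 0.16388 -0.13916 0.00000
ATOM CB1 C SC 0.17918 0.32574 0.00000
ATOM CB2 C SC 0.19689 0.38025 0.14186
ATOM NAM N SC 0.24201 0.51911 0.14186
ATOM HAM H SC 0.25719 0.56582 0.05361
ATOM CAM C SC 0.26381 0.58620 0.25520
ATOM OAM O SC 0.24707 0.53469 0.36574
ATOM CMA C SC 0.31053 0.72999 0.23957
ATOM OME O SC -0.35965 0.20765 0.00000
ATOM CME C SC -0.35346 0.34951 0.00000
ANCHOR N1 C2 C3
DONOR N1 HN1
DONOR NAM HAM
ACCEPTOR OAM
ACCEPTOR OME
RING C3A,C4,C5,C6,C7,C7A
RING N1,C2,C3,C3A,C7A
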