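# Molecular graphs of the 20 free (unpolymerized) natural amino acids.
# Explicit hydrogens; aromatic rings in a fixed Kekule form; neutral protonation.
# Format: 'RESIDUE <one-letter>' / 'ATOMS <symbols>' / 'BOND <i> <j> <order>' (0-based).
RESIDUE A
ATOMS C C N C O O H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 1 3 1
BOND 3 4 2
BOND 3 5 1
BOND 0 6 1
BOND 0 7 1
BOND 0 8 1
BOND 1 9 1
BOND 2 10 1
BOND 2 11 1
BOND 5 12 1
RESIDUE C
ATOMS S C C N C O O H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 1
BOND 2 4 1
BOND 4 5 2
BOND 4 6 1
BOND 0 7 1
BOND 1 8 1
BOND 1 9 1
BOND 2 10 1
BOND 3 11 1
BOND 3 12 1
BOND 6 13 1
RESIDUE D
ATOMS O C O C C N C O O H H H H H H H
BOND 0 1 1
BOND 1 2 2
BOND 1 3 1
BOND 3 4 1
BOND 4 5 1
BOND 4 6 1
BOND 6 7 2
BOND 6 8 1
BOND 0 9 1
BOND 3 10 1
BOND 3 11 1
BOND 4 12 1
BOND 5 13 1
BOND 5 14 1
BOND 8 15 1
RESIDUE E
ATOMS O C O C C C N C O O H H H H H H H H H
BOND 0 1 1
BOND 1 2 2
BOND 1 3 1
BOND 3 4 1
BOND 4 5 1
BOND 5 6 1
BOND 5 7 1
BOND 7 8 2
BOND 7 9 1
BOND 0 10 1
BOND 3 11 1
BOND 3 12 1
BOND 4 13 1
BOND 4 14 1
BOND 5 15 1
BOND 6 16 1
BOND 6 17 1
BOND 9 18 1
RESIDUE F
ATOMS N C C C C C C C C C O O H H H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 1
BOND 3 4 2
BOND 4 5 1
BOND 5 6 2
BOND 6 7 1
BOND 7 8 2
BOND 1 9 1
BOND 9 10 2
BOND 9 11 1
BOND 8 3 1
BOND 0 12 1
BOND 0 13 1
BOND 1 14 1
BOND 2 15 1
BOND 2 16 1
BOND 4 17 1
BOND 5 18 1
BOND 6 19 1
BOND 7 20 1
BOND 8 21 1
BOND 11 22 1
RESIDUE G
ATOMS N C C O O H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 2
BOND 2 4 1
BOND 0 5 1
BOND 0 6 1
BOND 1 7 1
BOND 1 8 1
BOND 4 9 1
RESIDUE H
ATOMS O C O C N C C C N C N H H H H H H H H H
BOND 0 1 1
BOND 1 2 2
BOND 1 3 1
BOND 3 4 1
BOND 3 5 1
BOND 5 6 1
BOND 6 7 2
BOND 7 8 1
BOND 8 9 1
BOND 9 10 2
BOND 10 6 1
BOND 0 11 1
BOND 3 12 1
BOND 4 13 1
BOND 4 14 1
BOND 5 15 1
BOND 5 16 1
BOND 7 17 1
BOND 8 18 1
BOND 9 19 1
RESIDUE I
ATOMS C C C C C N C O O H H H H H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 1
BOND 2 4 1
BOND 4 5 1
BOND 4 6 1
BOND 6 7 2
BOND 6 8 1
BOND 0 9 1
BOND 0 10 1
BOND 0 11 1
BOND 1 12 1
BOND 1 13 1
BOND 2 14 1
BOND 3 15 1
BOND 3 16 1
BOND 3 17 1
BOND 4 18 1
BOND 5 19 1
BOND 5 20 1
BOND 8 21 1
RESIDUE K
ATOMS N C C C C C N C O O H H H H H H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 1
BOND 3 4 1
BOND 4 5 1
BOND 5 6 1
BOND 5 7 1
BOND 7 8 2
BOND 7 9 1
BOND 0 10 1
BOND 0 11 1
BOND 1 12 1
BOND 1 13 1
BOND 2 14 1
BOND 2 15 1
BOND 3 16 1
BOND 3 17 1
BOND 4 18 1
BOND 4 19 1
BOND 5 20 1
BOND 6 21 1
BOND 6 22 1
BOND 9 23 1
RESIDUE L
ATOMS C C C C C N C O O H H H H H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 1 3 1
BOND 3 4 1
BOND 4 5 1
BOND 4 6 1
BOND 6 7 2
BOND 6 8 1
BOND 0 9 1
BOND 0 10 1
BOND 0 11 1
BOND 1 12 1
BOND 2 13 1
BOND 2 14 1
BOND 2 15 1
BOND 3 16 1
BOND 3 17 1
BOND 4 18 1
BOND 5 19 1
BOND 5 20 1
BOND 8 21 1
RESIDUE M
ATOMS C S C C C N C O O H H H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 1
BOND 3 4 1
BOND 4 5 1
BOND 4 6 1
BOND 6 7 2
BOND 6 8 1
BOND 0 9 1
BOND 0 10 1
BOND 0 11 1
BOND 2 12 1
BOND 2 13 1
BOND 3 14 1
BOND 3 15 1
BOND 4 16 1
BOND 5 17 1
BOND 5 18 1
BOND 8 19 1
RESIDUE N
ATOMS N C O C C N C O O H H H H H H H H
BOND 0 1 1
BOND 1 2 2
BOND 1 3 1
BOND 3 4 1
BOND 4 5 1
BOND 4 6 1
BOND 6 7 2
BOND 6 8 1
BOND 0 9 1
BOND 0 10 1
BOND 3 11 1
BOND 3 12 1
BOND 4 13 1
BOND 5 14 1
BOND 5 15 1
BOND 8 16 1
RESIDUE P
ATOMS O C O C C C C N H H H H H H H H H
BOND 0 1 1
BOND 1 2 2
BOND 1 3 1
BOND 3 4 1
BOND 4 5 1
BOND 5 6 1
BOND 6 7 1
BOND 7 3 1
BOND 0 8 1
BOND 3 9 1
BOND 4 10 1
BOND 4 11 1
BOND 5 12 1
BOND 5 13 1
BOND 6 14 1
BOND 6 15 1
BOND 7 16 1
RESIDUE Q
ATOMS N C O C C C N C O O H H H H H H H H H H
BOND 0 1 1
BOND 1 2 2
BOND 1 3 1
BOND 3 4 1
BOND 4 5 1
BOND 5 6 1
BOND 5 7 1
BOND 7 8 2
BOND 7 9 1
BOND 0 10 1
BOND 0 11 1
BOND 3 12 1
BOND 3 13 1
BOND 4 14 1
BOND 4 15 1
BOND 5 16 1
BOND 6 17 1
BOND 6 18 1
BOND 9 19 1
RESIDUE R
ATOMS N C C C C N C N N C O O H H H H H H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 1
BOND 3 4 1
BOND 4 5 1
BOND 5 6 1
BOND 6 7 2
BOND 6 8 1
BOND 1 9 1
BOND 9 10 2
BOND 9 11 1
BOND 0 12 1
BOND 0 13 1
BOND 1 14 1
BOND 2 15 1
BOND 2 16 1
BOND 3 17 1
BOND 3 18 1
BOND 4 19 1
BOND 4 20 1
BOND 5 21 1
BOND 7 22 1
BOND 8 23 1
BOND 8 24 1
BOND 11 25 1
RESIDUE S
ATOMS O C C N C O O H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 1
BOND 2 4 1
BOND 4 5 2
BOND 4 6 1
BOND 0 7 1
BOND 1 8 1
BOND 1 9 1
BOND 2 10 1
BOND 3 11 1
BOND 3 12 1
BOND 6 13 1
RESIDUE T
ATOMS C C O C N C O O H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 1 3 1
BOND 3 4 1
BOND 3 5 1
BOND 5 6 2
BOND 5 7 1
BOND 0 8 1
BOND 0 9 1
BOND 0 10 1
BOND 1 11 1
BOND 2 12 1
BOND 3 13 1
BOND 4 14 1
BOND 4 15 1
BOND 7 16 1
RESIDUE V
ATOMS C C C C N C O O H H H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 1 3 1
BOND 3 4 1
BOND 3 5 1
BOND 5 6 2
BOND 5 7 1
BOND 0 8 1
BOND 0 9 1
BOND 0 10 1
BOND 1 11 1
BOND 2 12 1
BOND 2 13 1
BOND 2 14 1
BOND 3 15 1
BOND 4 16 1
BOND 4 17 1
BOND 7 18 1
RESIDUE W
ATOMS N C C C C N C C C C C C C O O H H H H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 1
BOND 3 4 2
BOND 4 5 1
BOND 5 6 1
BOND 6 7 2
BOND 7 8 1
BOND 8 9 2
BOND 9 10 1
BOND 10 11 2
BOND 1 12 1
BOND 12 13 2
BOND 12 14 1
BOND 11 3 1
BOND 11 6 1
BOND 0 15 1
BOND 0 16 1
BOND 1 17 1
BOND 2 18 1
BOND 2 19 1
BOND 4 20 1
BOND 5 21 1
BOND 7 22 1
BOND 8 23 1
BOND 9 24 1
BOND 10 25 1
BOND 14 26 1
RESIDUE Y
ATOMS N C C C C C C O C C C O O H H H H H H H H H H H
BOND 0 1 1
BOND 1 2 1
BOND 2 3 1
BOND 3 4 2
BOND 4 5 1
BOND 5 6 2
BOND 6 7 1
BOND 6 8 1
BOND 8 9 2
BOND 1 10 1
BOND 10 11 2
BOND 10 12 1
BOND 9 3 1
BOND 0 13 1
BOND 0 14 1
BOND 1 15 1
BOND 2 16 1
BOND 2 17 1
BOND 4 18 1
BOND 5 19 1
BOND 7 20 1
BOND 8 21 1
BOND 9 22 1
BOND 12 23 1
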