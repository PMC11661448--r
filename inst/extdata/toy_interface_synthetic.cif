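data_toy_interface_synthetic
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1 N N . ALA A 1 1 ? 1.301 -0.663 -0.900 1.00 0.00 ? 1 ALA A N 1
ATOM 2 C CA . ALA A 1 1 ? 2.300 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1
ATOM 3 C C . ALA A 1 1 ? 1.483 0.723 1.050 1.00 0.00 ? 1 ALA A C 1
ATOM 4 O O . ALA A 1 1 ? 1.696 1.060 2.200 1.00 0.00 ? 1 ALA A O 1
ATOM 5 C CB . ALA A 1 1 ? 3.250 -0.573 -0.450 1.00 0.00 ? 1 ALA A CB 1
ATOM 6 N N . ALA A 1 2 ? 0.427 1.396 0.600 1.00 0.00 ? 2 ALA A N 1
ATOM 7 C CA . ALA A 1 2 ? -0.399 2.265 1.500 1.00 0.00 ? 2 ALA A CA 1
ATOM 8 C C . ALA A 1 2 ? -0.970 1.335 2.550 1.00 0.00 ? 2 ALA A C 1
ATOM 9 O O . ALA A 1 2 ? -1.338 1.486 3.700 1.00 0.00 ? 2 ALA A O 1
ATOM 10 C CB . ALA A 1 2 ? 0.000 3.300 1.050 1.00 0.00 ? 2 ALA A CB 1
ATOM 11 N N . ALA A 1 3 ? -1.449 0.178 2.100 1.00 0.00 ? 3 ALA A N 1
ATOM 12 C CA . ALA A 1 3 ? -2.161 -0.787 3.000 1.00 0.00 ? 3 ALA A CA 1
ATOM 13 C C . ALA A 1 3 ? -1.146 -1.187 4.050 1.00 0.00 ? 3 ALA A C 1
ATOM 14 O O . ALA A 1 3 ? -1.231 -1.576 5.200 1.00 0.00 ? 3 ALA A O 1
ATOM 15 C CB . ALA A 1 3 ? -3.250 -0.573 2.550 1.00 0.00 ? 3 ALA A CB 1
ATOM 16 N N . ALA A 1 4 ? 0.076 -1.458 3.600 1.00 0.00 ? 4 ALA A N 1
ATOM 17 C CA . ALA A 1 4 ? 1.150 -1.992 4.500 1.00 0.00 ? 4 ALA A CA 1
ATOM 18 C C . ALA A 1 4 ? 1.368 -0.923 5.550 1.00 0.00 ? 4 ALA A C 1
ATOM 19 O O . ALA A 1 4 ? 1.766 -0.939 6.700 1.00 0.00 ? 4 ALA A O 1
ATOM 20 C CB . ALA A 1 4 ? 1.129 -3.101 4.050 1.00 0.00 ? 4 ALA A CB 1
ATOM 21 N N . ALA A 1 5 ? 1.423 0.328 5.100 1.00 0.00 ? 5 ALA A N 1
ATOM 22 C CA . ALA A 1 5 ? 1.762 1.478 6.000 1.00 0.00 ? 5 ALA A CA 1
ATOM 23 C C . ALA A 1 5 ? 0.671 1.507 7.050 1.00 0.00 ? 5 ALA A C 1
ATOM 24 O O . ALA A 1 5 ? 0.618 1.902 8.200 1.00 0.00 ? 5 ALA A O 1
ATOM 25 C CB . ALA A 1 5 ? 2.858 1.650 5.550 1.00 0.00 ? 5 ALA A CB 1
ATOM 26 N N . ALA A 1 6 ? -0.570 1.344 6.600 1.00 0.00 ? 6 ALA A N 1
ATOM 27 C CA . ALA A 1 6 ? -1.762 1.478 7.500 1.00 0.00 ? 6 ALA A CA 1
ATOM 28 C C . ALA A 1 6 ? -1.601 0.399 8.550 1.00 0.00 ? 6 ALA A C 1
ATOM 29 O O . ALA A 1 6 ? -1.981 0.278 9.700 1.00 0.00 ? 6 ALA A O 1
ATOM 30 C CB . ALA A 1 6 ? -2.121 2.528 7.050 1.00 0.00 ? 6 ALA A CB 1
ATOM 31 N N . ALA A 1 7 ? -1.224 -0.795 8.100 1.00 0.00 ? 7 ALA A N 1
ATOM 32 C CA . ALA A 1 7 ? -1.150 -1.992 9.000 1.00 0.00 ? 7 ALA A CA 1
ATOM 33 C C . ALA A 1 7 ? -0.115 -1.646 10.050 1.00 0.00 ? 7 ALA A C 1
ATOM 34 O O . ALA A 1 7 ? 0.070 -1.999 11.200 1.00 0.00 ? 7 ALA A O 1
ATOM 35 C CB . ALA A 1 7 ? -2.121 -2.528 8.550 1.00 0.00 ? 7 ALA A CB 1
ATOM 36 N N . ALA A 1 8 ? 0.996 -1.068 9.600 1.00 0.00 ? 8 ALA A N 1
ATOM 37 C CA . ALA A 1 8 ? 2.161 -0.787 10.500 1.00 0.00 ? 8 ALA A CA 1
ATOM 38 C C . ALA A 1 8 ? 1.641 0.172 11.550 1.00 0.00 ? 8 ALA A C 1
ATOM 39 O O . ALA A 1 8 ? 1.956 0.416 12.700 1.00 0.00 ? 8 ALA A O 1
ATOM 40 C CB . ALA A 1 8 ? 2.858 -1.650 10.050 1.00 0.00 ? 8 ALA A CB 1
ATOM 41 N N . ALA B 1 1 ? 9.153 -0.663 -0.900 1.00 0.00 ? 1 ALA B N 1
ATOM 42 C CA . ALA B 1 1 ? 8.154 0.000 0.000 1.00 0.00 ? 1 ALA B CA 1
ATOM 43 C C . ALA B 1 1 ? 8.971 0.723 1.050 1.00 0.00 ? 1 ALA B C 1
ATOM 44 O O . ALA B 1 1 ? 8.758 1.060 2.200 1.00 0.00 ? 1 ALA B O 1
ATOM 45 C CB . ALA B 1 1 ? 7.249 -0.474 -0.450 1.00 0.00 ? 1 ALA B CB 1
ATOM 46 N N . ALA B 1 2 ? 10.027 1.396 0.600 1.00 0.00 ? 2 ALA B N 1
ATOM 47 C CA . ALA B 1 2 ? 10.853 2.265 1.500 1.00 0.00 ? 2 ALA B CA 1
ATOM 48 C C . ALA B 1 2 ? 11.424 1.335 2.550 1.00 0.00 ? 2 ALA B C 1
ATOM 49 O O . ALA B 1 2 ? 11.792 1.486 3.700 1.00 0.00 ? 2 ALA B O 1
ATOM 50 C CB . ALA B 1 2 ? 10.444 3.293 1.050 1.00 0.00 ? 2 ALA B CB 1
ATOM 51 N N . ALA B 1 3 ? 11.903 0.178 2.100 1.00 0.00 ? 3 ALA B N 1
ATOM 52 C CA . ALA B 1 3 ? 12.615 -0.787 3.000 1.00 0.00 ? 3 ALA B CA 1
ATOM 53 C C . ALA B 1 3 ? 11.600 -1.187 4.050 1.00 0.00 ? 3 ALA B C 1
ATOM 54 O O . ALA B 1 3 ? 11.685 -1.576 5.200 1.00 0.00 ? 3 ALA B O 1
ATOM 55 C CB . ALA B 1 3 ? 13.624 -0.552 2.550 1.00 0.00 ? 3 ALA B CB 1
ATOM 56 N N . ALA B 1 4 ? 10.377 -1.458 3.600 1.00 0.00 ? 4 ALA B N 1
ATOM 57 C CA . ALA B 1 4 ? 9.304 -1.992 4.500 1.00 0.00 ? 4 ALA B CA 1
ATOM 58 C C . ALA B 1 4 ? 9.086 -0.923 5.550 1.00 0.00 ? 4 ALA B C 1
ATOM 59 O O . ALA B 1 4 ? 8.688 -0.939 6.700 1.00 0.00 ? 4 ALA B O 1
ATOM 60 C CB . ALA B 1 4 ? 9.382 -3.052 4.050 1.00 0.00 ? 4 ALA B CB 1
ATOM 61 N N . ALA B 1 5 ? 9.031 0.328 5.100 1.00 0.00 ? 5 ALA B N 1
ATOM 62 C CA . ALA B 1 5 ? 8.692 1.478 6.000 1.00 0.00 ? 5 ALA B CA 1
ATOM 63 C C . ALA B 1 5 ? 9.783 1.507 7.050 1.00 0.00 ? 5 ALA B C 1
ATOM 64 O O . ALA B 1 5 ? 9.836 1.902 8.200 1.00 0.00 ? 5 ALA B O 1
ATOM 65 C CB . ALA B 1 5 ? 7.600 1.630 5.550 1.00 0.00 ? 5 ALA B CB 1
ATOM 66 N N . ALA B 1 6 ? 11.024 1.344 6.600 1.00 0.00 ? 6 ALA B N 1
ATOM 67 C CA . ALA B 1 6 ? 12.216 1.478 7.500 1.00 0.00 ? 6 ALA B CA 1
ATOM 68 C C . ALA B 1 6 ? 12.055 0.399 8.550 1.00 0.00 ? 6 ALA B C 1
ATOM 69 O O . ALA B 1 6 ? 12.434 0.278 9.700 1.00 0.00 ? 6 ALA B O 1
ATOM 70 C CB . ALA B 1 6 ? 12.568 2.476 7.050 1.00 0.00 ? 6 ALA B CB 1
ATOM 71 N N . ALA B 1 7 ? 11.678 -0.795 8.100 1.00 0.00 ? 7 ALA B N 1
ATOM 72 C CA . ALA B 1 7 ? 11.604 -1.992 9.000 1.00 0.00 ? 7 ALA B CA 1
ATOM 73 C C . ALA B 1 7 ? 10.569 -1.646 10.050 1.00 0.00 ? 7 ALA B C 1
ATOM 74 O O . ALA B 1 7 ? 10.384 -1.999 11.200 1.00 0.00 ? 7 ALA B O 1
ATOM 75 C CB . ALA B 1 7 ? 12.539 -2.439 8.550 1.00 0.00 ? 7 ALA B CB 1
ATOM 76 N N . ALA B 1 8 ? 9.458 -1.068 9.600 1.00 0.00 ? 8 ALA B N 1
ATOM 77 C CA . ALA B 1 8 ? 8.292 -0.787 10.500 1.00 0.00 ? 8 ALA B CA 1
ATOM 78 C C . ALA B 1 8 ? 8.813 0.172 11.550 1.00 0.00 ? 8 ALA B C 1
ATOM 79 O O . ALA B 1 8 ? 8.497 0.416 12.700 1.00 0.00 ? 8 ALA B O 1
ATOM 80 C CB . ALA B 1 8 ? 7.608 -1.766 10.050 1.00 0.00 ? 8 ALA B CB 1
#
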