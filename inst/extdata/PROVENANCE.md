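# Bundled reference tables

`random_coil_shifts.csv` — average backbone random-coil chemical shifts
(ppm) for the 20 standard amino acids (CA, CB, CO, H, N; Gly has no CB,
Pro no amide H/N). Values are compiled from standard literature
random-coil reference tables at 0.1 ppm-level precision; they are package
conventions suitable for secondary-chemical-shift analysis of disordered
proteins, not a new measurement. Users working with sequence-corrected or
temperature/pH-corrected references should pass their own table to
`compute_scs()` (same columns: `residue_type, atom, shift_ppm`).

`secondary_structure_reference.csv` — deviations from random coil (ppm)
expected for fully formed alpha-helix (`helix_delta`) and beta-strand
(`strand_delta`) for CA, CB and CO. The deviations are average values
applied uniformly across residue types (rows kept residue-specific so a
user-supplied residue-dependent table is a drop-in replacement). They set
the +1/-1 normalization of the secondary-structure-propensity scale.
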