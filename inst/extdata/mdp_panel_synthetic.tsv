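# Bundled mitochondrial-derived-peptide (MDP) panel metadata.
# mode=homology entries are searched by local protein alignment of candidate
# ORF peptides against the panel peptide, restricted to the anchor locus and
# strand. mode=positional entries (Rudel) are defined structurally: the
# longest antisense ORF of the anchor locus, with no reference peptide.
# SEQUENCE PROVENANCE: MOTS-c and Humanin carry the canonical human peptide
# sequences (UniProt A0A0B4J2F0 and Q8IVG9). All entries marked
# source=synthetic_surrogate carry seeded synthetic stand-in peptides, NOT
# the human sequences: suitable for exercising the pipeline against the
# bundled synthetic reference, and meant to be replaced by a user-supplied
# panel FASTA/TSV for analyses of real genomes.
# expected_orf_len_nt is the nominal ORF length reported in the literature
# for the named peptide (36 nt for MOTS-c); NA where unknown.
name	mode	anchor_gene	anchor_strand	expected_orf_len_nt	source
MOTS-c	homology	mt-Rnr1	sense	36	human_UniProt_A0A0B4J2F0
Humanin	homology	mt-Rnr2	sense	75	human_UniProt_Q8IVG9
SHLP1	homology	mt-Rnr2	sense	72	synthetic_surrogate
SHLP2	homology	mt-Rnr2	antisense	78	synthetic_surrogate
SHLP3	homology	mt-Rnr2	sense	114	synthetic_surrogate
SHLP4	homology	mt-Rnr2	antisense	78	synthetic_surrogate
SHLP5	homology	mt-Rnr2	sense	72	synthetic_surrogate
SHLP6	homology	mt-Rnr2	antisense	60	synthetic_surrogate
SHMOOSE	homology	mt-Nd5	antisense	174	synthetic_surrogate
MTALTND4	homology	mt-Nd4	sense	297	synthetic_surrogate
Gau	homology	mt-Co1	antisense	300	synthetic_surrogate
CYTB-187AA	homology	mt-Cyb	sense	561	synthetic_surrogate
Rudel	positional	mt-Atp6/8	antisense	663	structural_definition
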