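Package: mitotome
Title: Extended Mitochondrial Transcriptome Construction and Hibernation
    Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an extended mitochondrial reference transcriptome for a
    circular mitochondrial genome: classical mRNAs and rRNAs from a GenBank
    feature table, mitochondrial-derived-peptide (MDP) ORFs predicted by
    local protein alignment against a bundled peptide panel, a nested
    antisense ORF caller for the mt-Atp8/mt-Atp6 locus, and template-placed
    long non-coding RNAs; poly-A-incompatible tRNAs are excluded and the
    manifest is written to FASTA/GFF3. Downstream, it profiles
    transcript-quantification output: mitochondrial read fraction,
    moderated-log detection filtering, negative-binomial likelihood-ratio
    differential expression across hibernation states with a sex covariate,
    Benjamini-Hochberg adjustment, and per-state direction calls. A
    synthetic-data module generates circular genomes with planted
    annotation truth and negative-binomial count matrices with planted
    design effects so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    GenomicRanges,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
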