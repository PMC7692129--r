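# Minimal benchmark design in the documented YAML schema.
# Coordinates: variant positions are 1-based; roi/panel intervals are
# 0-based half-open (BED convention).
benchmark_id: "EXAMPLE/1"
participants: [LAB01, LAB02, LAB03, LAB04, LAB05, LAB06]
validation_policy: ddPCR_or_WES
samples:
  - sample_id: EX-001
    cancer_context: colorectal carcinoma (advanced stage)
    replicate_count: 3
    targeted_genes: [BRAF, KRAS, NRAS]
ordered_variants:
  - sample_id: EX-001
    gene: BRAF
    transcript: NM_004333.4
    protein_ref: NP_004324.2
    p_hgvs: p.(Val600Glu)
    c_hgvs: c.1799T>A
    chrom: chr7
    pos: 140453136
    expected_af: 13.2
    validation: ddPCR
    origin: endogenous
  - sample_id: EX-001
    gene: KRAS
    p_hgvs: p.(Ala146Thr)
    chrom: chr12
    pos: 25378562
    expected_af: 20.1
    validation: ddPCR
    origin: inserted
    cassette:
      start: 25377561
      end: 25379561
roi:
  - {chrom: chr7, start: 140453000, end: 140453300, name: BRAF_ex15}
  - {chrom: chr12, start: 25378400, end: 25378700, name: KRAS_ex4}
panels:
  - panel_id: PNL-AMP
    enrichment: amplicon
    intervals:
      - {chrom: chr7, start: 140453050, end: 140453250, name: amp_braf}
      - {chrom: chr12, start: 25378450, end: 25378650, name: amp_kras}
panel_assignments:
  LAB01: PNL-AMP
  LAB02: PNL-AMP
  LAB03: PNL-AMP
  LAB04: PNL-AMP
  LAB05: PNL-AMP
  LAB06: PNL-AMP
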