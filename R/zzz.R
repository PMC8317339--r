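#' @keywords internal
"_PACKAGE"

# data.table NSE columns
utils::globalVariables(c(
  ".", "..key", "A", "C", "G", "N", "ad", "agreement_fraction", "alt",
  "bam", "base_quality", "bin", "canon", "chan", "change_pct", "class",
  "cls", "count", "degenerate", "depth", "df", "dist", "dist_from_breakpoint",
  "eligible_bases", "errors", "family_id", "family_size", "flag", "frag",
  "fragment_end", "fragment_start", "fragment_strand", "grp",
  "higher_group", "i.canon", "m1", "m2", "mapq", "mate", "n", "n1", "n2",
  "n_vot", "n_voting", "obs_base", "off", "ok", "p", "p_adj", "pair_id",
  "pnext", "pos", "qname", "qpos", "qual", "rate", "read_id", "ref",
  "ref_base", "removed_quality", "retained_eligible", "rk", "row", "rx",
  "sample_id", "sample_type", "se2", "significant", "t", "tlen", "umi",
  "v1", "v2", "bases_post_des", "rate_before", "rate_after"))
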