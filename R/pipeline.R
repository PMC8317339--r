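#' Build a run manifest
#'
#' Collects everything one profiling run needs: the sample sheet, file
#' paths, and filter settings. [simulate_reads()] returns a ready-made
#' manifest; for real data, construct one from your own sample sheet.
#'
#' @param samples `data.frame` with columns `sample_id`, `sample_type`
#'   (`cfDNA`/`gDNA`), `pair_id`, `bam`, and optionally `subject_id`,
#'   `replicate_id`.
#' @param reference Reference FASTA path.
#' @param panel_bed Target-panel BED path.
#' @param filter A [filter_config()].
#' @return A validated `run_manifest` list.
#' @export
run_manifest <- function(samples, reference, panel_bed,
                         filter = filter_config()) {
  samples <- as.data.table(samples)
  need <- c("sample_id", "sample_type", "pair_id", "bam")
  if (!all(need %in% names(samples)))
    stop("samples needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids")
  if (!all(samples$sample_type %in% c("cfDNA", "gDNA")))
    stop("sample_type must be cfDNA or gDNA")
  # rule 4 is pairwise: every pair id must hold one cfDNA and one gDNA
  chk <- samples[, .(ok = .N == 2 && setequal(sample_type, c("cfDNA", "gDNA"))),
                 by = pair_id]
  if (!all(chk$ok))
    stop("incomplete cfDNA/gDNA pair(s): ",
         paste(chk[ok == FALSE]$pair_id, collapse = ", "))
  for (p in c(reference, panel_bed, samples$bam))
    if (!file.exists(p)) stop("missing file: ", p)
  structure(list(samples = samples, reference = reference,
                 panel_bed = panel_bed, filter = filter),
            class = "run_manifest")
}

as_run_manifest <- function(x) {
  if (inherits(x, "run_manifest")) return(x)
  if (is.list(x) && !is.null(x$samples) && !is.null(x$reference))
    return(run_manifest(x$samples, x$reference, x$panel_bed))
  stop("cannot interpret object as a run manifest")
}

# partner sample id for each sample id
pair_map <- function(samples) {
  m <- samples[, if (.N == 2) .(a = sample_id[1], b = sample_id[2]),
               by = pair_id]
  setNames(c(m$b, m$a), c(m$a, m$b))
}

#' Profile every sample in a manifest
#'
#' The full per-sample pipeline: stream observations over the panel,
#' group UMI families and collapse to consensus (unless `des = FALSE`),
#' tally site counts under the quality rule, mask germline alleles
#' pairwise, and compute the error profile, error-free fraction, and
#' fragment-bin profile under the joint depth rule. A per-rule attrition
#' table accounts for every observed base.
#'
#' @param manifest A `run_manifest` (or [simulate_reads()] result).
#' @param des Collapse UMI families before counting (default `TRUE`).
#'   With `des = "both"`, raw profiles are computed alongside and
#'   [des_effect()] reductions reported.
#' @param denominator Passed to [compute_error_profile()].
#' @param verbose Print per-sample progress.
#' @return List with `profiles`, `counts`, `masks`, `bin_profiles`,
#'   `error_free`, `attrition`, `des_reduction` (when `des = "both"`),
#'   `meta`, and the `filter` used.
#' @export
run_profile <- function(manifest, des = TRUE,
                        denominator = "opportunity", verbose = FALSE) {
  manifest <- as_run_manifest(manifest)
  filter <- manifest$filter
  samples <- manifest$samples
  panel <- load_panel(manifest$panel_bed)
  partner <- pair_map(samples)

  counts <- masks <- bins <- raw_counts <- list()
  attrition <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    if (verbose) message("profiling ", sid)
    obs <- stream_observations(samples$bam[i], panel, manifest$reference)
    bases_in <- nrow(obs)
    if (isTRUE(des) || des == "both") {
      grouped <- group_families(obs)
      cons <- des_consensus(grouped)
      if (des == "both") raw_counts[[sid]] <- build_site_counts(obs, filter)
      work <- cons
    } else {
      work <- obs
    }
    n_lowq <- nrow(work[base_quality < filter$min_base_quality])
    counts[[sid]] <- build_site_counts(work, filter)
    bins[[sid]] <- list(obs = NULL, profile = NULL)
    # bin profile needs the observations; fill in after masks are known
    bins[[sid]]$obs <- work
    attrition[[sid]] <- data.table(
      sample_id = sid, bases_in = bases_in,
      bases_post_des = nrow(work),
      removed_quality = n_lowq)
  }

  for (sid in names(counts)) {
    masks[[sid]] <- apply_pairwise_variant_exclusion(
      counts[[sid]], counts[[partner[sid]]], filter)
  }

  profiles <- raw_profiles <- list()
  error_free <- setNames(numeric(length(counts)), names(counts))
  bin_profiles <- list()
  for (sid in names(counts)) {
    pc <- counts[[partner[sid]]]
    profiles[[sid]] <- compute_error_profile(
      counts[[sid]], masks[[sid]], filter, pair_counts = pc,
      sample_id = sid, denominator = denominator)
    error_free[sid] <- error_free_fraction(counts[[sid]], masks[[sid]],
                                           filter, pair_counts = pc)
    bin_profiles[[sid]] <- fragment_bin_profile(
      bins[[sid]]$obs, masks[[sid]], filter, counts = counts[[sid]],
      pair_counts = pc, sample_id = sid)
    if (des == "both") {
      raw_profiles[[sid]] <- compute_error_profile(
        raw_counts[[sid]], masks[[sid]], filter, pair_counts = raw_counts[[partner[sid]]],
        sample_id = sid, denominator = denominator)
    }
    retained <- sum(profiles[[sid]]$eligible_bases)
    attrition[[sid]][, `:=`(
      retained_eligible = retained,
      removed_depth_rule = bases_post_des - removed_quality - retained)]
    bins[[sid]]$obs <- NULL
  }
  attrition <- rbindlist(attrition)

  des_reduction <- NULL
  if (des == "both")
    des_reduction <- rbindlist(lapply(names(profiles), function(sid)
      des_effect(raw_profiles[[sid]], profiles[[sid]])[, sample_id := sid]))

  list(profiles = profiles, counts = counts, masks = masks,
       bin_profiles = bin_profiles, error_free = error_free,
       attrition = attrition, des_reduction = des_reduction,
       meta = samples, filter = filter, pair_of = partner)
}

#' Run all group comparisons on a profiling result
#'
#' Produces every statistical output of the analysis: class-wise
#' cfDNA-vs-gDNA tests (directional and collapsed), per-position tests
#' with the hit list, the exclude-and-reprofile deltas, breakpoint-bin
#' contrasts, and (when replicates are labelled) replicate concordance.
#'
#' @param prof Result of [run_profile()].
#' @param alpha_class,alpha_pos Significance levels for the class-wise
#'   and positional tests.
#' @param correction Positional multiple-testing correction (see
#'   [compare_positions()]).
#' @return List with `class_comparison`, `class_comparison_collapsed`,
#'   `position_comparison`, `exclusion`, `bin_comparison`,
#'   `replicate_concordance` (or `NULL`).
#' @export
run_compare <- function(prof, alpha_class = 0.01, alpha_pos = 0.05,
                        correction = "bonferroni") {
  groups <- setNames(prof$meta$sample_type, prof$meta$sample_id)
  cls_cmp <- compare_class_rates(prof$profiles, groups, alpha = alpha_class)
  cls_cmp_coll <- compare_class_rates(prof$profiles, groups,
                                      alpha = alpha_class, collapsed = TRUE)
  pos_tab <- position_error_table(prof$counts, prof$masks, prof$filter)
  pos_cmp <- compare_positions(pos_tab, groups, alpha = alpha_pos,
                               correction = correction)
  excl <- exclude_and_reprofile(pos_cmp$hits, prof$counts, prof$masks,
                                prof$filter, pair_of = prof$pair_of)
  bin_cmp <- compare_bins(prof$bin_profiles, groups)
  rep_conc <- NULL
  if ("replicate_id" %in% names(prof$meta) &&
      length(unique(prof$meta$replicate_id)) == 2) {
    rep_conc <- replicate_concordance(
      prof$profiles, setNames(prof$meta$replicate_id, prof$meta$sample_id))
  }
  list(class_comparison = cls_cmp,
       class_comparison_collapsed = cls_cmp_coll,
       position_table = pos_tab,
       position_comparison = pos_cmp,
       exclusion = excl,
       bin_comparison = bin_cmp,
       replicate_concordance = rep_conc)
}

#' Write the main report tables of a run
#'
#' Emits per-sample profile TSVs (with JSON sidecars), bin-profile TSVs,
#' the class-comparison table, the positional hit list (TSV and BED), and
#' the attrition log into a directory.
#'
#' @param prof Result of [run_profile()].
#' @param cmp Result of [run_compare()] (optional).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(prof, cmp = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(prof$profiles)) {
    write_error_profile(prof$profiles[[sid]],
                        file.path(dir, paste0(sid, ".profile.tsv")),
                        extra = list(min_base_quality = prof$filter$min_base_quality,
                                     min_depth = prof$filter$min_depth,
                                     germline_af_threshold = prof$filter$germline_af_threshold))
    write_bin_profile(prof$bin_profiles[[sid]],
                      file.path(dir, paste0(sid, ".bins.tsv")))
  }
  fwrite(prof$attrition, file.path(dir, "attrition.tsv"), sep = "\t")
  fwrite(data.table(sample_id = names(prof$error_free),
                    error_free_pct = as.numeric(prof$error_free)),
         file.path(dir, "error_free.tsv"), sep = "\t")
  if (!is.null(prof$des_reduction))
    fwrite(prof$des_reduction, file.path(dir, "des_reduction.tsv"), sep = "\t")
  if (!is.null(cmp)) {
    fwrite(cmp$class_comparison$classes,
           file.path(dir, "class_comparison.tsv"), sep = "\t")
    fwrite(cmp$class_comparison$total,
           file.path(dir, "class_comparison_total.tsv"), sep = "\t")
    fwrite(cmp$position_comparison$hits,
           file.path(dir, "position_hits.tsv"), sep = "\t")
    hits <- cmp$position_comparison$hits
    if (nrow(hits) > 0) {
      bed <- hits[, .(chrom, start = pos - 1L, end = pos,
                      name = class, score = pmin(1000L, as.integer(-10 * log10(
                        pmax(p_adj, 1e-100)))))]
      fwrite(bed, file.path(dir, "position_hits.bed"), sep = "\t",
             col.names = FALSE)
    }
    fwrite(cmp$bin_comparison$bin1_vs_rest,
           file.path(dir, "bin1_vs_rest.tsv"), sep = "\t")
    fwrite(cmp$exclusion$deltas, file.path(dir, "exclusion_deltas.tsv"),
           sep = "\t")
  }
  invisible(dir)
}
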