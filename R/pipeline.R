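#' End-to-end comparative hypomethylome run on a simulated composite genome
#'
#' Orchestrates every stage: simulate the composite genome and two host
#' contexts' BioCAP replicates plus input controls; call HMRs per replicate
#' and keep replicate-reproducible peaks; correct for rearrangements; build
#' the cross-context union and classify each HMR as shared or
#' species-specific by the fold rule; profile CpG density/GC against a
#' shifted background; estimate summit repeat ages; annotate TSS proximity
#' and species-specific TF binding; and validate a sample of HMRs with
#' simulated bisulfite counts and spike-in conversion QC. Every intermediate
#' is written to `outdir` and a machine-readable JSON report is produced.
#' The run is fully determined by the config seed.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param peak_params,diff_params,ann_params,age_params Stage parameter
#'   objects.
#' @param n_bisulfite_amplicons How many classified HMRs (spread over the
#'   label classes) to re-assay with simulated bisulfite counts.
#' @return A list of class `hmr_run_report` (also written as
#'   `report.json`), invisibly containing all stage outputs.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         peak_params = peak_call_params(),
                         diff_params = differential_params(),
                         ann_params = annotation_params(),
                         age_params = repeat_age_params(),
                         n_bisulfite_amplicons = 6L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  bundle <- stage("simulate", {
    b <- simulate_composite_genome(config)
    write_fasta(b$sequences, file.path(outdir, "genome.fa"))
    write_bed(b$element_truth, file.path(outdir, "element_truth.bed"),
              extra_cols = c("class", "mechanism"))
    write_repeats(b$repeat_truth, file.path(outdir, "repeats.bed"))
    if (nrow(b$tss_truth) > 0) {
      write_bed(interval_tbl(b$tss_truth$contig, b$tss_truth$pos,
                             b$tss_truth$pos + 1, name = b$tss_truth$name,
                             strand = b$tss_truth$strand),
                file.path(outdir, "tss.bed"))
    }
    b
  })

  contexts <- c("A", "B")
  tracks <- stage("coverage", {
    out <- list()
    for (k in seq_along(contexts)) {
      ctx <- contexts[k]
      reps <- lapply(1:2, function(r) {
        trk <- simulate_biocap_coverage(bundle, ctx,
                                        replicate_seed = config$seed + 10L * k + r)
        write_bedgraph(trk, file.path(outdir,
                                      sprintf("biocap_%s_rep%d.bedGraph", ctx, r)))
        trk
      })
      input <- simulate_input_control(bundle, seed = config$seed + 100L + k)
      write_bedgraph(input, file.path(outdir,
                                      sprintf("input_%s.bedGraph", ctx)))
      pooled <- coverage_track(reps[[1]]$contig,
                               reps[[1]]$values + reps[[2]]$values,
                               reps[[1]]$total_reads + reps[[2]]$total_reads,
                               attr(reps[[1]], "fragment_length"))
      out[[ctx]] <- list(reps = reps, input = input, pooled = pooled)
    }
    out
  })

  hmrs_by_context <- stage("callhmr", {
    out <- list()
    for (ctx in contexts) {
      peaks <- lapply(tracks[[ctx]]$reps, call_peaks,
                      control = tracks[[ctx]]$input, params = peak_params)
      reproducible <- intersect_replicates(peaks[[1]], peaks[[2]])
      corrected <- apply_rearrangement_map(reproducible,
                                           bundle$rearrangement_map)
      write_bed(corrected, file.path(outdir, sprintf("hmrs_%s.bed", ctx)),
                extra_cols = c("summit", "p_value", "n_reads"))
      out[[ctx]] <- corrected
    }
    out
  })

  classified <- stage("classify", {
    union <- merge_union(hmrs_by_context$A, hmrs_by_context$B)
    if (nrow(union) == 0L) {
      cls <- NULL
    } else {
      cls <- classify_hmrs(union, tracks$A$pooled, tracks$B$pooled,
                           diff_params)
      cls <- apply_rearrangement_map(cls, bundle$rearrangement_map)
      write_bed(cls, file.path(outdir, "hmrs_classified.bed"),
                extra_cols = c("label", "n_a", "n_b_normalized", "fold"))
      readr::write_tsv(as_tibble(cls)[, c("name", "n_a", "n_b_normalized",
                                          "label")],
                       file.path(outdir, "scatter_counts.tsv"))
    }
    cls
  })

  features <- stage("profile", {
    if (is.null(classified)) NULL else {
    ft <- hmr_feature_table(classified, bundle$sequences)
    bg <- shifted_background(classified, nchar(bundle$sequences[[.TRANSPLANT]]),
                             excluded = classified, seed = config$seed + 31L)
    ft_bg <- hmr_feature_table(bg, bundle$sequences)
    ft_bg$label <- "background"
    readr::write_tsv(bind_rows(ft, ft_bg),
                     file.path(outdir, "feature_table.tsv"))
    list(hmrs = ft, background = ft_bg)
    }
  })

  ages <- stage("repeat_age", {
    if (is.null(classified)) NULL else {
    cmp <- if (sum(classified$label == "B_specific") > 0 &&
               sum(classified$label == "shared") > 0)
      c("shared", "B_specific") else NULL
    prof <- summit_repeat_ages(classified, bundle$repeat_truth, age_params,
                               compare = cmp)
    readr::write_tsv(prof$samples, file.path(outdir, "repeat_ages.tsv"))
    prof
    }
  })

  annotation <- stage("annotate", {
    if (is.null(classified)) NULL else {
    tssd <- classify_tss_proximity(classified, bundle$tss_truth, ann_params)
    ssp <- species_specific_peaks(bundle$tf_truth_by_context$A,
                                  bundle$tf_truth_by_context$B)
    tf_overlap <- list()
    for (ctx in contexts) {
      targets <- tssd[tssd$label == paste0(ctx, "_specific"), ]
      spec_peaks <- ssp[ssp$context == ctx & ssp$status == "specific", ]
      if (nrow(targets) > 0 && nrow(spec_peaks) > 0) {
        tf_overlap[[ctx]] <- multiway_overlap_summary(
          targets, split(spec_peaks, spec_peaks$factor))
      }
    }
    list(tss = tssd, tf_peaks = ssp, tf_overlap = tf_overlap)
    }
  })

  bisulfite <- stage("bisulfite", {
    if (is.null(classified)) NULL else {
    picks <- classified |>
      group_by(.data$label) |>
      dplyr::slice_head(n = max(1L, n_bisulfite_amplicons %/% 3L)) |>
      ungroup()
    amps <- interval_tbl(picks$contig, picks$start, picks$end,
                         name = picks$name)
    bs <- lapply(setNames(contexts, contexts), function(ctx) {
      simulate_bisulfite_counts(bundle, ctx, amps,
                                seed = config$seed + 200L + match(ctx, contexts))
    })
    qc <- conversion_efficiency(bs$A$spike_unmeth, bs$A$spike_meth)
    summaries <- lapply(bs, function(x) summarize_amplicons(x$calls, amps))
    for (ctx in contexts) {
      readr::write_tsv(summaries[[ctx]]$per_cpg,
                       file.path(outdir, sprintf("bisulfite_%s.tsv", ctx)))
    }
    readr::write_tsv(qc, file.path(outdir, "bisulfite_qc.tsv"))
    list(summaries = summaries, qc = qc, amplicons = amps,
         labels = picks$label)
    }
  })

  report <- stage("report", {
    n_lab <- function(lab) if (is.null(classified)) 0L
      else sum(classified$label == lab)
    recap <- function(x, y) {
      if (nrow(x) == 0L) return(NA_real_)
      mean(interval_overlaps_any(x, y))
    }
    tss_frac <- if (is.null(annotation)) NULL else {
      annotation$tss |>
        group_by(.data$label) |>
        summarise(fraction_tss = mean(.data$tss_associated),
                  .groups = "drop")
    }
    rep <- list(
      seed = config$seed,
      transplant_length = config$transplant_length,
      n_hmrs = list(A = nrow(hmrs_by_context$A), B = nrow(hmrs_by_context$B)),
      n_union = if (is.null(classified)) 0L else nrow(classified),
      n_by_label = list(shared = n_lab("shared"),
                        A_specific = n_lab("A_specific"),
                        B_specific = n_lab("B_specific")),
      fraction_shared = if (is.null(classified)) NA_real_
        else n_lab("shared") / nrow(classified),
      fraction_a_recapitulated_in_b = recap(hmrs_by_context$A,
                                            hmrs_by_context$B),
      fraction_b_recapitulated_in_a = recap(hmrs_by_context$B,
                                            hmrs_by_context$A),
      tss_fraction_by_label = tss_frac,
      tf_overlap_percent = lapply(
        annotation$tf_overlap %||% list(),
        function(x) x$percent_any),
      bisulfite_conversion = if (is.null(bisulfite)) NA_real_
        else bisulfite$qc$conversion,
      bisulfite_qc_pass = if (is.null(bisulfite)) NA
        else bisulfite$qc$qc_pass
    )
    jsonlite::write_json(rep, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows", na = "null")
    rep
  })

  invisible(structure(
    list(report = report, bundle = bundle, hmrs_by_context = hmrs_by_context,
         classified = classified, features = features, ages = ages,
         annotation = annotation, bisulfite = bisulfite, outdir = outdir),
    class = "hmr_run_report"))
}

#' @export
print.hmr_run_report <- function(x, ...) {
  r <- x$report
  cat("<hmr_run_report>\n")
  cat(sprintf("  HMRs: A=%d, B=%d; union=%d (shared=%d, A-specific=%d, B-specific=%d)\n",
              r$n_hmrs$A, r$n_hmrs$B, r$n_union, r$n_by_label$shared,
              r$n_by_label$A_specific, r$n_by_label$B_specific))
  cat(sprintf("  fraction shared: %.3f; A recapitulated in B: %.3f\n",
              r$fraction_shared, r$fraction_a_recapitulated_in_b))
  cat(sprintf("  outputs in %s\n", x$outdir))
  invisible(x)
}
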