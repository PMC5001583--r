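#' @title Composite-genome simulation internals
#' @name sim-genome-internals
#' @noRd
NULL

.BASES <- c("A", "C", "G", "T")

.random_bases <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(.BASES, n, replace = TRUE, prob = p)
}

.cg_starts <- function(bases) {
  n <- length(bases)
  if (n < 2L) return(integer(0))
  which(bases[-n] == "C" & bases[-1] == "G")
}

# Thin CpG dinucleotides down to `rate` per bp by replacing the G of dropped
# CpGs with A/T (which cannot create a new CpG).
.thin_cpgs <- function(bases, rate) {
  cg <- .cg_starts(bases)
  if (length(cg) == 0L) return(bases)
  keep_p <- min(1, rate * length(bases) / length(cg))
  drop <- cg[runif(length(cg)) > keep_p]
  if (length(drop) > 0L) {
    bases[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
  }
  bases
}

.background_seq <- function(n, cpg_rate, gc = 0.5) {
  .thin_cpgs(.random_bases(n, gc), cpg_rate)
}

# Element sequence with an exactly controlled CpG count: strip every CpG from
# a GC-biased background, then write round(rate * len) CG dinucleotides at
# non-adjacent positions.
.element_seq <- function(len, cpg_rate, gc = 0.55) {
  bases <- .thin_cpgs(.random_bases(len, gc), 0)
  k <- round(cpg_rate * len)
  if (k > 0L) {
    cand <- seq(1L, len - 1L, by = 2L)
    pos <- sort(sample(cand, min(k, length(cand))))
    bases[pos] <- "C"
    bases[pos + 1L] <- "G"
  }
  bases
}

# Greedy rejection placement of `lengths` on a contig of length L, keeping
# `gap` bp between elements and `margin` bp off both ends. Returns 0-based
# starts in input order.
.place_elements <- function(lengths, L, margin = NULL, gap = NULL,
                            max_tries = 10000L) {
  n <- length(lengths)
  if (n == 0L) return(numeric(0))
  margin <- margin %||% min(10000L, L %/% 20L)
  gap <- gap %||% min(2000L, L %/% 50L)
  need <- sum(lengths) + gap * n + 2 * margin
  if (need > L) {
    abort(sprintf(paste0(
      "planted element footprints (%d elements, %s bp incl. spacing) exceed ",
      "transplant_length (%s bp); reduce the element counts or lengths"),
      n, format(need, big.mark = ","), format(L, big.mark = ",")))
  }
  starts <- numeric(n)
  acc_s <- numeric(0)
  acc_e <- numeric(0)
  for (i in seq_len(n)) {
    len <- lengths[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(L - len - 2 * margin + 1L, 1L) + margin - 1L  # 0-based
      if (all(s >= acc_e + gap | s + len + gap <= acc_s)) {
        starts[i] <- s
        acc_s <- c(acc_s, s)
        acc_e <- c(acc_e, s + len)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "could not place element %d of %d (length %d bp) after %d tries; the contig is too crowded",
        i, n, len, max_tries))
    }
  }
  starts
}

.TRANSPLANT <- "chrT"
.HOST <- "chrHost"
.SPIKE_UNMETH <- "spikein_unmeth"
.SPIKE_METH <- "spikein_meth"
.TF_FACTORS <- c("CEBPA", "HNF4A", "CTCF")

#' Simulate a composite genome with planted methylome ground truth
#'
#' Generates one transplanted contig (`chrT`) carrying non-overlapping planted
#' elements -- shared CGIs hypomethylated in both host contexts, young
#' CpG-rich repeats hypomethylated only in the context lacking a repeat
#' defence, and TF-protected low-CpG distal elements bound in only one
#' context -- plus a background host contig and two synthetic 10 kb
#' conversion-control spike-in contigs. Per-CpG methylation probabilities are
#' drawn Beta(`hmr_meth`) inside a context's hypomethylated elements and
#' Beta(`background_meth`) everywhere else, independently per context.
#'
#' @param config A [sim_config()].
#' @return A list of class `genome_bundle` with components `sequences` (named
#'   character vector of uppercase DNA), `element_truth` (all planted
#'   hypomethylated elements with `class` and `mechanism`), `cgi_truth`,
#'   `repeat_truth` (with `family` and `millidiv`), `tss_truth`,
#'   `tf_truth_by_context` (list `A`/`B` of TF peak tibbles),
#'   `methylome_by_context` (list `A`/`B` of per-CpG tibbles `contig`, `pos`,
#'   `m`), `rearrangement_map`, and the `config`.
#' @examples
#' bundle <- simulate_composite_genome(sim_config(
#'   transplant_length = 2e5, n_shared_cgis = 6, n_a_specific = 2,
#'   n_b_specific = 2, n_young_repeats = 2, n_old_repeats = 2
#' ))
#' bundle$element_truth
#' @export
simulate_composite_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, .simulate_composite_genome(config))
}

.simulate_composite_genome <- function(cfg) {
  L <- cfg$transplant_length

  n_arep <- min(cfg$n_young_repeats %/% 2L, cfg$n_a_specific)
  n_brep <- min(cfg$n_young_repeats %/% 2L, cfg$n_b_specific)
  n_atf <- cfg$n_a_specific - n_arep
  n_btf <- cfg$n_b_specific - n_brep

  plan <- tibble(
    class = c(rep("shared", cfg$n_shared_cgis),
              rep("A_specific", n_arep), rep("A_specific", n_atf),
              rep("B_specific", n_brep), rep("B_specific", n_btf)),
    mechanism = c(rep("cgi", cfg$n_shared_cgis),
                  rep("young_repeat", n_arep), rep("tf_protected", n_atf),
                  rep("young_repeat", n_brep), rep("tf_protected", n_btf))
  )
  cgi_lens <- seq(cfg$cgi_length_range[1], cfg$cgi_length_range[2])
  plan$length <- dplyr::case_when(
    plan$mechanism == "cgi" ~ cgi_lens[sample.int(length(cgi_lens),
                                                  nrow(plan), replace = TRUE)],
    plan$mechanism == "young_repeat" ~ rep(cfg$repeat_length, nrow(plan)),
    TRUE ~ rep(cfg$tf_element_length, nrow(plan))
  )
  plan$cpg_rate <- dplyr::case_when(
    plan$mechanism == "cgi" ~ cfg$cgi_cpg_rate,
    plan$mechanism == "young_repeat" ~ cfg$repeat_cpg_rate,
    TRUE ~ cfg$tf_element_cpg_rate
  )
  plan$gc <- ifelse(plan$mechanism == "tf_protected", 0.45, 0.55)

  n_tfspec <- c(A = n_atf, B = n_btf)
  n_shared_tf <- max(0L, cfg$n_tf_sites_per_context - max(n_tfspec))
  # annotation-only placements: shared TF sites and rearrangement features
  neutral <- tibble(
    kind = c(rep("shared_tf", n_shared_tf),
             rep("deletion", cfg$n_deletions),
             rep("duplication", cfg$n_duplications),
             rep("breakpoint", cfg$n_breakpoints)),
    length = c(rep(300L, n_shared_tf),
               rep(5000L, cfg$n_deletions),
               rep(5000L, cfg$n_duplications),
               rep(100L, cfg$n_breakpoints))
  )

  all_len <- c(plan$length, neutral$length)
  starts <- .place_elements(all_len, L)
  plan$start <- starts[seq_len(nrow(plan))]
  plan$end <- plan$start + plan$length
  neutral$start <- starts[nrow(plan) + seq_len(nrow(neutral))]
  neutral$end <- neutral$start + neutral$length

  # --- transplanted contig sequence ---------------------------------------
  bases <- .background_seq(L, cfg$background_cpg_rate)
  for (i in seq_len(nrow(plan))) {
    idx <- (plan$start[i] + 1L):plan$end[i]
    bases[idx] <- .element_seq(plan$length[i], plan$cpg_rate[i], plan$gc[i])
  }
  # re-thin the junctions: writing an element can abut a C/G at its edges
  for (i in seq_len(nrow(plan))) {
    for (j in c(plan$start[i], plan$end[i])) {
      if (j >= 1L && j < L && bases[j] == "C" && bases[j + 1L] == "G") {
        bases[j + 1L] <- "A"
      }
    }
  }

  sequences <- c(
    setNames(paste(bases, collapse = ""), .TRANSPLANT),
    setNames(paste(.background_seq(cfg$host_length, cfg$background_cpg_rate),
                   collapse = ""), .HOST),
    setNames(paste(.background_seq(cfg$spike_length, 0.02), collapse = ""),
             .SPIKE_UNMETH),
    setNames(paste(.background_seq(cfg$spike_length, 0.02), collapse = ""),
             .SPIKE_METH)
  )

  # --- truth tables --------------------------------------------------------
  mk_name <- function(class, mechanism) {
    key <- paste(substr(class, 1, 1), mechanism, sep = "_")
    idx <- stats::ave(seq_along(key), key, FUN = seq_along)
    sprintf("%s_%02d", key, idx)
  }
  element_truth <- tibble(
    contig = .TRANSPLANT,
    start = as.numeric(plan$start),
    end = as.numeric(plan$end),
    name = if (nrow(plan)) mk_name(plan$class, plan$mechanism) else character(),
    class = plan$class,
    mechanism = plan$mechanism,
    length = as.numeric(plan$length)
  ) |> arrange(.data$start)

  cgi_truth <- element_truth |>
    filter(.data$class == "shared") |>
    select("contig", "start", "end", "name")

  # young repeats = the planted young-repeat elements; old repeats annotated
  # at the centres of a random subset of shared CGIs
  young <- element_truth |> filter(.data$mechanism == "young_repeat")
  n_old <- min(cfg$n_old_repeats, nrow(cgi_truth))
  old_host <- if (n_old > 0L) {
    cgi_truth[sort(sample.int(nrow(cgi_truth), n_old)), ]
  } else cgi_truth[0, ]
  old <- tibble(
    contig = old_host$contig,
    start = pmax(old_host$start,
                 floor((old_host$start + old_host$end) / 2) - 300),
    end = pmin(old_host$end,
               floor((old_host$start + old_host$end) / 2) + 300),
    name = sprintf("old_rep_%02d", seq_len(nrow(old_host)))
  )
  repeat_truth <- bind_rows(
    tibble(contig = young$contig, start = young$start, end = young$end,
           name = paste0(young$name, "_rep"),
           family = rep_len(c("AluY_like", "L1PA_like"), nrow(young)),
           millidiv = if (nrow(young)) sample(0:50, nrow(young), TRUE)
                      else integer()),
    tibble(contig = old$contig, start = old$start, end = old$end,
           name = old$name,
           family = rep_len(c("L2_like", "MIR_like"), nrow(old)),
           millidiv = if (nrow(old)) sample(150:300, nrow(old), TRUE)
                      else integer())
  ) |> arrange(.data$start)

  n_tss <- round(cfg$tss_fraction * nrow(cgi_truth))
  tss_host <- if (n_tss > 0L) {
    cgi_truth[sort(sample.int(nrow(cgi_truth), n_tss)), ]
  } else cgi_truth[0, ]
  tss_truth <- tibble(contig = tss_host$contig, pos = tss_host$start,
                      strand = "+",
                      name = sub("^s_cgi", "tss", tss_host$name))

  shared_tf <- neutral |> filter(.data$kind == "shared_tf")
  tf_truth_by_context <- lapply(c(A = "A", B = "B"), function(ctx) {
    spec <- element_truth |>
      filter(.data$class == paste0(ctx, "_specific"),
             .data$mechanism == "tf_protected")
    bind_rows(
      tibble(contig = spec$contig, start = spec$start, end = spec$end,
             factor = rep_len(.TF_FACTORS, nrow(spec)),
             name = paste0(spec$name, "_tf"), context = ctx),
      tibble(contig = .TRANSPLANT, start = as.numeric(shared_tf$start),
             end = as.numeric(shared_tf$end),
             factor = rep_len(.TF_FACTORS, nrow(shared_tf)),
             name = sprintf("shared_tf_%02d", seq_len(nrow(shared_tf))),
             context = ctx)
    ) |> arrange(.data$start)
  })

  rearrangement_map <- rearrangement_map(
    breakpoints = if (cfg$n_breakpoints)
      floor((neutral$start + neutral$end)[neutral$kind == "breakpoint"] / 2)
      else numeric(0),
    deleted = neutral |> filter(.data$kind == "deletion") |>
      (\(d) interval_tbl(.TRANSPLANT, d$start, d$end))(),
    duplicated = neutral |> filter(.data$kind == "duplication") |>
      (\(d) {
        x <- interval_tbl(.TRANSPLANT, d$start, d$end)
        x$copy_number <- rep(2L, nrow(x))
        x
      })()
  )

  # --- methylomes ----------------------------------------------------------
  host_bases <- strsplit(sequences[[.HOST]], "")[[1]]
  cpg_t <- .cg_starts(bases) - 1L          # 0-based C positions
  cpg_h <- .cg_starts(host_bases) - 1L
  draw_methylome <- function(ctx) {
    hypo <- element_truth |>
      filter(.data$class %in% c("shared", paste0(ctx, "_specific")))
    m_t <- rbeta(length(cpg_t), cfg$background_meth[1], cfg$background_meth[2])
    if (nrow(hypo) > 0L && length(cpg_t) > 0L) {
      inside <- interval_overlaps_any(
        tibble(contig = .TRANSPLANT, start = cpg_t, end = cpg_t + 1), hypo)
      m_t[inside] <- rbeta(sum(inside), cfg$hmr_meth[1], cfg$hmr_meth[2])
    }
    m_h <- rbeta(length(cpg_h), cfg$background_meth[1], cfg$background_meth[2])
    bind_rows(
      tibble(contig = .TRANSPLANT, pos = as.numeric(cpg_t), m = m_t),
      tibble(contig = .HOST, pos = as.numeric(cpg_h), m = m_h)
    )
  }
  methylome_by_context <- list(A = draw_methylome("A"), B = draw_methylome("B"))

  structure(
    list(sequences = sequences,
         element_truth = element_truth,
         cgi_truth = cgi_truth,
         repeat_truth = repeat_truth,
         tss_truth = tss_truth,
         tf_truth_by_context = tf_truth_by_context,
         methylome_by_context = methylome_by_context,
         rearrangement_map = rearrangement_map,
         config = cfg),
    class = "genome_bundle"
  )
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("<genome_bundle>\n")
  cat(sprintf("  contigs: %s\n",
              paste(sprintf("%s (%s bp)", names(x$sequences),
                            format(nchar(x$sequences), big.mark = ",")),
                    collapse = ", ")))
  cat(sprintf("  planted elements: %d (%s)\n", nrow(x$element_truth),
              paste(sprintf("%s=%d", names(table(x$element_truth$class)),
                            table(x$element_truth$class)), collapse = ", ")))
  cat(sprintf("  CpGs on %s: %d\n", .TRANSPLANT,
              sum(x$methylome_by_context$A$contig == .TRANSPLANT)))
  invisible(x)
}
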