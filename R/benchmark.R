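#' Run the full benchmark over one or more tools
#'
#' Orchestrates the downstream analyses for each tool: threshold sweeps
#' (interaction counts, bait-bait proportion, fraction of baits with at
#' least one interaction, percentage decrease relative to the loosest
#' cutoff), replicate reproducibility per threshold and extension pad,
#' functional overlap with peak tracks per feature and pad, and,
#' when full unthresholded tables are supplied, the joint
#' mean-threshold comparison.
#'
#' @param tools Named list; each element is a list with `call_sets`
#'   (list of >= 2 `call_set`s, one per replicate) and optionally
#'   `lf = TRUE` to apply per-bait local filtering first (q-value
#'   metric only).
#' @param map,baits The shared `fragment_map` and `bait_map`.
#' @param qvalue_cutoffs,score_cutoffs Threshold sweeps per metric
#'   kind; the first entry is the loosest, reference cutoff.
#' @param pads Other-end extension pads in bases.
#' @param peaks Optional peaks (`GRanges` with `label`, or a list).
#' @param full_tables Optional named list (by tool) of per-replicate
#'   full result tables for [joint_mean_pass()].
#' @param min_support Replicate-support rule (default 2).
#' @return An object of class `benchmark_report`: list of data.frames
#'   `counts`, `reproducibility`, `functional`, `joint`, `lf_summary`
#'   plus a `manifest` list echoing every setting used.
#' @export
run_benchmark <- function(tools, map, baits,
                          qvalue_cutoffs = c(0.05, 0.01, 0.001),
                          score_cutoffs = c(5, 10, 15),
                          pads = c(0L, 2500L, 20000L),
                          peaks = NULL, full_tables = NULL,
                          min_support = 2L) {
  if (length(tools) < 1L || is.null(names(tools))) {
    cb_stop("tools must be a non-empty named list",
            class = "chicbench_config_error")
  }
  counts_tab <- list(); repro_tab <- list(); func_tab <- list()
  joint_tab <- list(); lf_tab <- list()
  for (tool in names(tools)) {
    entry <- tools[[tool]]
    css <- entry$call_sets
    if (length(css) < 2L) {
      cb_stop("tool ", tool, " needs >= 2 replicates",
              class = "chicbench_config_error")
    }
    css <- lapply(css, function(cs) {
      cs$tool <- tool
      classify_calls(cs, baits)
    })
    if (isTRUE(entry$lf)) {
      lf_res <- lapply(css, local_filter)
      css <- lapply(lf_res, `[[`, "calls")
      for (k in seq_along(lf_res)) {
        thr <- lf_res[[k]]$thresholds
        lf_tab[[length(lf_tab) + 1L]] <- data.frame(
          tool = tool, replicate = css[[k]]$replicate,
          n_baits = nrow(thr), n_input = sum(thr$n_input),
          n_retained = sum(thr$n_retained),
          retained_fraction = sum(thr$n_retained) / sum(thr$n_input))
      }
    }
    kind <- css[[1L]]$metric_kind
    cutoffs <- if (kind == "qvalue") qvalue_cutoffs else score_cutoffs
    loosest <- cutoffs[1L]
    n_loosest <- NULL
    for (cut in cutoffs) {
      spec <- metric_spec(kind, cut)
      thresholded <- lapply(css, apply_threshold, spec = spec)
      ns <- vapply(thresholded, function(x) nrow(x$calls), numeric(1))
      if (cut == loosest) n_loosest <- ns
      for (k in seq_along(thresholded)) {
        cs <- thresholded[[k]]
        counts_tab[[length(counts_tab) + 1L]] <- data.frame(
          tool = tool, replicate = cs$replicate, metric_kind = kind,
          cutoff = cut, n_interactions = nrow(cs$calls),
          prop_bait_bait = bait_bait_proportion(cs),
          frac_baits_with_interaction =
            fraction_baits_with_interaction(cs, baits),
          pct_decrease_vs_loosest =
            100 * (n_loosest[k] - nrow(cs$calls)) / n_loosest[k])
      }
      for (pad in pads) {
        st <- support_table(thresholded, pad = pad, map = map)
        rf <- reproducibility_fraction(st, min_support)
        repro_tab[[length(repro_tab) + 1L]] <- data.frame(
          tool = tool, metric_kind = kind, cutoff = cut, pad = pad,
          n_union = nrow(st), fraction = rf$fraction,
          per_replicate_mean = rf$per_replicate_mean)
      }
    }
    if (!is.null(peaks)) {
      spec <- metric_spec(kind, loosest)
      for (pad in pads) {
        for (cs in lapply(css, apply_threshold, spec = spec)) {
          fo <- functional_overlap_fraction(cs, peaks, pad, map)
          func_tab[[length(func_tab) + 1L]] <- cbind(
            data.frame(tool = tool, replicate = cs$replicate, pad = pad,
                       n_fragments = fo$n_fragments),
            fo$per_feature)
        }
      }
    }
    if (!is.null(full_tables[[tool]])) {
      jm <- joint_mean_pass(full_tables[[tool]],
                            metric_spec(kind, loosest))
      joint_tab[[length(joint_tab) + 1L]] <- data.frame(
        tool = tool, metric_kind = kind, cutoff = loosest,
        n_joint = jm$n_joint, n_indiv_union = jm$n_indiv_union,
        increase = jm$increase)
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  structure(list(
    counts = bind(counts_tab),
    reproducibility = bind(repro_tab),
    functional = bind(func_tab),
    joint = bind(joint_tab),
    lf_summary = bind(lf_tab),
    manifest = list(
      tools = names(tools),
      replicates = lapply(tools, function(t) {
        vapply(t$call_sets, function(x) x$replicate, character(1))
      }),
      qvalue_cutoffs = qvalue_cutoffs, score_cutoffs = score_cutoffs,
      pads = pads, min_support = min_support,
      package_version = as.character(utils::packageVersion("chicbench")))),
    class = "benchmark_report")
}

#' Write a benchmark report to disk
#'
#' Emits one TSV per non-empty report table and a machine-readable
#' manifest.json. Output is deterministic: rerunning on identical
#' inputs reproduces identical files.
#'
#' @param report A [run_benchmark()] result.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_benchmark_report <- function(report, outdir) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (name in c("counts", "reproducibility", "functional", "joint",
                 "lf_summary")) {
    if (!is.null(report[[name]])) {
      write_tsv_plain(report[[name]],
                      file.path(outdir, paste0(name, ".tsv")),
                      header = TRUE)
    }
  }
  jsonlite::write_json(report$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>", paste(x$manifest$tools, collapse = ", "),
      "\n")
  for (name in c("counts", "reproducibility", "functional", "joint")) {
    if (!is.null(x[[name]])) {
      cat("$", name, ": ", nrow(x[[name]]), " rows\n", sep = "")
    }
  }
  invisible(x)
}
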