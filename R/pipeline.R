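PIPELINE_STAGES <- c("filter", "mask", "trim", "dedup", "samfilter", "rdsignal")

#' Pipeline configuration
#'
#' Describes an end-to-end preprocessing run: which stages to execute (in the
#' fixed order filter, mask, trim, dedup, samfilter, rdsignal; each stage is
#' individually skippable), their parameters, the inputs, and a global seed.
#' Alignment itself is a deliberate gap: a user-supplied SAM enters the
#' pipeline between the read stages and the alignment post-filters.
#'
#' @param input_fastq Path to the input FASTQ (read stages).
#' @param stages Character vector of stages to run.
#' @param out_dir Output directory (created if missing).
#' @param sam Path to a SAM file (required for `samfilter` / `rdsignal`).
#' @param reference FASTA path (required for `rdsignal`).
#' @param seed Global seed for the seeded stages.
#' @param filter,mask,trim,dedup,samfilter,rdsignal Named lists of per-stage
#'   parameter overrides (see the stage functions for names and defaults).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_fastq = NULL,
                            stages = c("filter", "mask"),
                            out_dir = tempfile("rdprep_run_"),
                            sam = NULL, reference = NULL, seed = 1L,
                            filter = list(), mask = list(), trim = list(),
                            dedup = list(), samfilter = list(),
                            rdsignal = list()) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0L) {
    rlang::abort(sprintf("unknown pipeline stage(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "rdprep_config_error")
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  needs_fastq <- any(stages %in% c("filter", "mask", "trim", "dedup"))
  if (needs_fastq && is.null(input_fastq)) {
    rlang::abort("input_fastq is required for the read stages",
                 class = "rdprep_config_error")
  }
  if (any(stages %in% c("samfilter", "rdsignal")) && is.null(sam)) {
    rlang::abort("a SAM file is required for the alignment stages",
                 class = "rdprep_config_error")
  }
  if ("rdsignal" %in% stages && is.null(reference)) {
    rlang::abort("a reference FASTA is required for the rdsignal stage",
                 class = "rdprep_config_error")
  }
  structure(list(input_fastq = input_fastq, stages = stages,
                 out_dir = out_dir, sam = sam, reference = reference,
                 seed = as.integer(seed),
                 params = list(filter = filter, mask = mask, trim = trim,
                               dedup = dedup, samfilter = samfilter,
                               rdsignal = rdsignal)),
            class = "pipeline_config")
}

#' Run the preprocessing pipeline
#'
#' Executes the enabled stages in order, writing each stage's output under
#' `out_dir` (FASTQ after each read stage, SAM after the alignment filters,
#' TSV + bedGraph for the read-depth track) together with a machine-readable
#' `report.json` capturing package version, parameters, seed and per-stage
#' counts. Reruns with an identical configuration reproduce identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly; element `artifacts` maps stage
#'   names to output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "rdprep",
                 version = as.character(utils::packageVersion("rdprep")),
                 seed = config$seed, stages = config$stages,
                 params = config$params, counts = list(), artifacts = list())
  p <- config$params

  reads <- NULL
  if (any(config$stages %in% c("filter", "mask", "trim", "dedup"))) {
    reads <- read_fastq(config$input_fastq)
    reads <- decode_qualities(reads)
    report$counts$input <- list(reads = nrow(reads))
  }
  write_stage <- function(reads, stage) {
    path <- file.path(config$out_dir, paste0(stage, ".fastq"))
    write_fastq(reads, path)
    path
  }

  for (stage in config$stages) {
    if (stage == "filter") {
      pol <- do.call(filter_policy, p$filter)
      reads <- filter_low_quality(reads, pol)
      report$counts$filter <- as.list(glance(reads))
      report$artifacts$filter <- write_stage(reads, "filter")
    } else if (stage == "mask") {
      reads <- do.call(mask_low_quality, c(list(reads), p$mask))
      report$counts$mask <- as.list(glance(reads))
      report$artifacts$mask <- write_stage(reads, "mask")
    } else if (stage == "trim") {
      spec <- do.call(adapter_spec, p$trim)
      reads <- trim_3prime(reads, spec)
      report$counts$trim <- as.list(glance(reads))
      report$artifacts$trim <- write_stage(reads, "trim")
    } else if (stage == "dedup") {
      pol <- do.call(dedup_policy, p$dedup)
      res <- dedup_library(reads, pol)
      reads <- res$reads
      report$counts$dedup <- as.list(res$stats)
      report$artifacts$dedup <- write_stage(reads, "dedup")
    } else if (stage == "samfilter") {
      aln <- read_sam(config$sam)
      args <- p$samfilter
      aln <- filter_mapq(aln, args$min_mapq %||% 0L)
      mapq_stats <- as.list(attr(aln, "stats"))
      aln <- resolve_multimappers(aln, args$multimap %||% "unique",
                                  seed = args$seed %||% config$seed)
      report$counts$samfilter <- c(mapq_stats, as.list(attr(aln, "stats")))
      path <- file.path(config$out_dir, "samfilter.sam")
      write_sam(aln, path)
      report$artifacts$samfilter <- path
      config$sam <- path
    } else if (stage == "rdsignal") {
      args <- p$rdsignal
      gc <- gc_signal(config$reference, args$window_len %||% 100L)
      aln <- read_sam(config$sam)
      track <- raw_rd(aln, gc, args$rule %||% "center")
      track <- gc_correct(track, args$scope %||% "chromosome")
      tsv <- file.path(config$out_dir, "rd_track.tsv")
      bg <- file.path(config$out_dir, "rd_track.bedgraph")
      write_track(track, tsv, bedgraph = bg)
      report$counts$rdsignal <- as.list(glance(track))
      report$artifacts$rdsignal <- tsv
    }
  }
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  report$artifacts$report <- report_path
  invisible(report)
}
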