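#' Write detection outputs to a directory
#'
#' Writes the standard result bundle: `pcgs.tsv` (one row per PCG: `pcg_id`,
#' `n_taxa`, `depth`, `prevalence`, `mean_pooled_relabund`,
#' semicolon-joined `members`), `membership.tsv` (`taxon_id` to `pcg_id`,
#' with `none` for taxa in no PCG) and `report.json`, a machine-readable
#' mirror of every number. Files are UTF-8 tab-separated with a trailing
#' newline; numbers carry 6 significant digits.
#'
#' @param pcgs a `pcg_set` from [find_pcgs()].
#' @param summary the matching [pcg_summary()].
#' @param report optional named list of extra objects to embed in
#'   `report.json` (e.g. a `ses_mpd` or `recovery_report` result).
#' @param out_dir output directory, created if needed.
#' @return character vector of the files written, invisibly.
#' @export
write_outputs <- function(pcgs, summary, report = NULL, out_dir) {
  stopifnot(inherits(pcgs, "pcg_set"), inherits(summary, "pcg_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  pcgs_path <- file.path(out_dir, "pcgs.tsv")
  memb_path <- file.path(out_dir, "membership.tsv")
  json_path <- file.path(out_dir, "report.json")

  pp <- summary$per_pcg
  df <- data.frame(
    pcg_id = pp$pcg_id, n_taxa = pp$n_taxa,
    depth = fmt_num(pp$depth), prevalence = fmt_num(pp$prevalence),
    mean_pooled_relabund = fmt_num(pp$mean_pooled_relabund),
    members = vapply(pcgs$pcgs, function(p)
      paste(p$member_taxa, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  write.table(df, pcgs_path, sep = "\t", quote = FALSE, row.names = FALSE)

  memb <- setNames(rep("none", length(pcgs$taxon_ids)), pcgs$taxon_ids)
  for (p in pcgs$pcgs) memb[p$member_taxa] <- p$pcg_id
  write.table(data.frame(taxon_id = names(memb), pcg_id = unname(memb),
                         stringsAsFactors = FALSE),
              memb_path, sep = "\t", quote = FALSE, row.names = FALSE)

  payload <- list(
    params = unclass(pcgs$params),
    n_samples = pcgs$n_samples,
    n_taxa = length(pcgs$taxon_ids),
    n_pcgs = length(pcgs$pcgs),
    mean_coverage = signif(summary$mean_coverage, 6),
    coverage = as.list(signif(summary$coverage, 6)),
    pcgs = lapply(seq_along(pcgs$pcgs), function(i) {
      p <- pcgs$pcgs[[i]]
      list(pcg_id = p$pcg_id, n_taxa = length(p$member_taxa),
           depth = signif(p$depth, 6),
           prevalence = signif(p$prevalence, 6),
           mean_pooled_relabund = signif(mean(p$pooled_relabund), 6),
           pooled_relabund = as.list(signif(p$pooled_relabund, 6)),
           dominants = as.list(summary$dominants[i, ]),
           members = p$member_taxa)
    }))
  if (!is.null(report)) payload$report <- report
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(pcgs_path, memb_path, json_path))
}

#' Write an SES-MPD result table as TSV
#' @param signal a `ses_mpd` data frame.
#' @param path output path (`signal.tsv` by convention).
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  df <- data.frame(sample_id = signal$sample_id, ntaxa = signal$ntaxa,
                   mpd_obs = fmt_num(signal$mpd_obs),
                   null_mean = fmt_num(signal$null_mean),
                   null_sd = fmt_num(signal$null_sd),
                   ses = fmt_num(signal$ses),
                   degenerate = signal$degenerate,
                   undefined = signal$undefined,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an intra-PCG turnover table as TSV
#' @param turnover a `pcg_turnover` data frame.
#' @param path output path (`turnover.tsv` by convention).
#' @return `path`, invisibly.
#' @export
write_turnover <- function(turnover, path) {
  df <- data.frame(pcg_id = turnover$pcg_id,
                   S_effective = turnover$S_effective,
                   f_mode = fmt_num(turnover$f_mode),
                   turnover = fmt_num(turnover$turnover),
                   dominants = turnover$dominants,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a recovery report (TSV + JSON)
#' @param report a `recovery_report`.
#' @param out_dir output directory, created if needed.
#' @return files written, invisibly.
#' @export
write_recovery <- function(report, out_dir) {
  stopifnot(inherits(report, "recovery_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(out_dir, "recovery.tsv")
  js <- file.path(out_dir, "recovery_summary.json")
  pc <- report$per_clade
  pc$jaccard <- fmt_num(pc$jaccard)
  write.table(pc, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(regime = report$regime, tau = report$tau,
         n_exact = report$n_exact, recall = report$recall,
         recall_exact = report$recall_exact, precision = report$precision,
         zero_detected = report$zero_detected,
         unmatched_detected = report$unmatched_detected),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
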