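#' Write a trial to a directory
#'
#' One directory per trial: `meta.yaml` (subject metadata and rates),
#' wide-format `kinematics.tsv` and `grf.tsv` (time plus named channels), and,
#' for synthetic trials, the ground truth as `truth.json`.
#'
#' @param trial a [mocap_trial].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "mocap_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(trial$meta, file.path(dir, "meta.yaml"))
  utils::write.table(trial$kin, file.path(dir, "kinematics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(trial$grf, file.path(dir, "grf.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(trial$truth))
    jsonlite::write_json(trial$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a trial directory
#'
#' @param dir a directory written by [write_trial] (or assembled by hand in
#'   the same layout).
#' @return A [mocap_trial].
#' @export
read_trial <- function(dir) {
  need <- c("meta.yaml", "kinematics.tsv", "grf.tsv")
  have <- file.exists(file.path(dir, need))
  if (!all(have))
    stop("trial directory ", dir, " is missing required file(s): ",
         paste(need[!have], collapse = ", "), call. = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  kin <- utils::read.delim(file.path(dir, "kinematics.tsv"))
  grf <- utils::read.delim(file.path(dir, "grf.tsv"))
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    if (!is.null(truth$steps)) truth$steps <- as.data.frame(truth$steps)
  }
  mocap_trial(kin, grf, meta, truth = truth)
}
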