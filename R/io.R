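## Result writers: plain tab-separated coordinate tables plus the diversity
## partition as JSON, matching what the command-line interface emits.

#' Write crossed-DPCoA results to a directory
#'
#' Writes `eigenvalues.tsv` (axis, eigenvalue, percent of retained total,
#' percent of the SS reference), the score tables `species_coords.tsv`,
#' `community_coords.tsv`, `levelA_coords.tsv`, `levelB_coords.tsv`, and
#' `partition.json` with the six quadratic-entropy components and their
#' percentages of SST.
#'
#' @param fit a [crossed_dpcoa()] object.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "crossed_dpcoa"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eig <- data.frame(axis = seq_along(fit$eig),
                    eigenvalue = fit$eig,
                    percent = fit$percent,
                    percent_of_ss = fit$percent_ss)
  utils::write.table(eig, file.path(dir, "eigenvalues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_coords <- function(m, path) {
    df <- data.frame(label = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_coords(fit$scores$species, file.path(dir, "species_coords.tsv"))
  write_coords(fit$scores$communities, file.path(dir, "community_coords.tsv"))
  write_coords(fit$scores$levelsA, file.path(dir, "levelA_coords.tsv"))
  write_coords(fit$scores$levelsB, file.path(dir, "levelB_coords.tsv"))
  write_partition_json(fit$partition, file.path(dir, "partition.json"))
  invisible(dir)
}

#' Write an ANOQE partition as JSON
#'
#' @param part an [anoqe()] object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_partition_json <- function(part, path) {
  stopifnot(inherits(part, "anoqe"))
  obj <- as.list(unclass(part))
  pct <- attr(part, "percent")
  names(pct) <- paste0(names(pct), "_percent")
  jsonlite::write_json(c(obj, as.list(pct)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
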