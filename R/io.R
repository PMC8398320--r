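#' @include AllClasses.R
NULL

# Fixture layout (one directory per dataset, plain text throughout):
#   dataset.json                 name, montage, fs, t0, class map, subject ids
#   subj_<id>.json               per-split dims and labels
#   subj_<id>_train.tsv, _test.tsv   tensors as [T*N x C] tab-separated
#                                matrices, trial-major, %.17g (bit-exact
#                                round trip for doubles)

writeTensor <- function(x, path) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 3, 2)), nrow = d[1] * d[3], ncol = d[2])
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

readTensor <- function(path, d) {
  v <- scan(path, what = double(), sep = "\t", quiet = TRUE)
  if (length(v) != prod(d))
    stop("tensor file ", basename(path), " has wrong size")
  m <- matrix(v, nrow = d[1] * d[3], ncol = d[2], byrow = TRUE)
  aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
}

#' Save a multi-subject dataset as a plain-text fixture directory
#'
#' Writes a self-describing directory: \code{dataset.json} with the shared
#' metadata (montage, fs, t0, class map), one JSON sidecar per subject with
#' dims and labels, and one tab-separated tensor file per split. Two saves
#' of the same dataset produce byte-identical payloads.
#'
#' @param d a \linkS4class{MultiSubjectDataset}.
#' @param path target directory (created if absent).
#' @return \code{path}, invisibly.
#' @seealso [loadDataset()]
#' @export
saveDataset <- function(d, path) {
  stopifnot(is(d, "MultiSubjectDataset"))
  validObject(d)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  e1 <- d@subjects[[1L]]$train
  meta <- list(
    format = "mipool-fixture-v1",
    name = d@name,
    montage = d@montage,
    fs = e1@fs,
    t0 = e1@t0,
    class_map = list(`1` = "left_hand", `2` = "right_hand"),
    subjects = names(d@subjects)
  )
  jsonlite::write_json(meta, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in names(d@subjects)) {
    s <- d@subjects[[id]]
    side <- list(
      train = list(dim = dim(s$train@data), labels = s$train@labels),
      test = list(dim = dim(s$test@data), labels = s$test@labels)
    )
    jsonlite::write_json(side, file.path(path, sprintf("subj_%s.json", id)),
                         digits = NA, pretty = TRUE)
    writeTensor(s$train@data, file.path(path, sprintf("subj_%s_train.tsv", id)))
    writeTensor(s$test@data, file.path(path, sprintf("subj_%s_test.tsv", id)))
  }
  invisible(path)
}

#' Load a multi-subject dataset from a fixture directory
#'
#' Inverse of [saveDataset()]; validates all dataset invariants (shared
#' montage, both classes present in every split, matching train/test label
#' sets). Subject order is deterministic (lexicographic id).
#'
#' @param path fixture directory.
#' @return A validated \linkS4class{MultiSubjectDataset}.
#' @export
loadDataset <- function(path) {
  metaFile <- file.path(path, "dataset.json")
  if (!file.exists(metaFile))
    stop("not a dataset fixture: missing ", metaFile)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  for (k in c("name", "montage", "fs", "t0", "subjects"))
    if (is.null(meta[[k]])) stop("dataset.json lacks required field '", k, "'")
  subs <- list()
  for (id in sort(meta$subjects)) {
    sideFile <- file.path(path, sprintf("subj_%s.json", id))
    if (!file.exists(sideFile)) stop("missing sidecar for subject ", id)
    side <- jsonlite::read_json(sideFile, simplifyVector = TRUE)
    mk <- function(split) {
      Epochs(readTensor(file.path(path, sprintf("subj_%s_%s.tsv", id, split)),
                        side[[split]]$dim),
             side[[split]]$labels, meta$fs, meta$montage, meta$t0)
    }
    subs[[id]] <- list(train = mk("train"), test = mk("test"))
  }
  d <- multiSubjectDataset(subs, name = meta$name, montage = meta$montage)
  validObject(d)
  d
}
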