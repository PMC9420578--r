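## Plain-text interchange: delimited recordings with YAML sidecars, epoch
## directories with a manifest, feature CSVs, and a full-precision
## structured text format for trained models.

#' @importFrom yaml write_yaml read_yaml
NULL

fmtNum <- function(x) sprintf("%.17g", x)

#' Write / read a recording as delimited text
#'
#' `writeRecordingText()` writes `<path>.tsv` (samples x channels, header
#' row of channel labels) and a `<path>.yaml` sidecar carrying the sampling
#' rate, subject id and condition id. `readRecordingText()` reads the pair
#' back.
#'
#' @param rec an [EEGRecording-class].
#' @param path file path without extension.
#' @return `writeRecordingText()` returns `path` invisibly;
#'   `readRecordingText()` returns an [EEGRecording-class].
#' @export
writeRecordingText <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  m <- t(rec@data)
  colnames(m) <- rec@channelLabels
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_yaml(list(fs = rec@fs, subjectId = rec@subjectId,
                  conditionId = rec@conditionId,
                  channelLabels = as.list(rec@channelLabels)),
             paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeRecordingText
#' @export
readRecordingText <- function(path) {
  meta <- read_yaml(paste0(path, ".yaml"))
  m <- as.matrix(utils::read.table(paste0(path, ".tsv"), header = TRUE,
                                   sep = "\t", check.names = FALSE))
  dimnames(m) <- NULL
  eegRecording(t(m), fs = meta$fs, channelLabels = unlist(meta$channelLabels),
               subjectId = meta$subjectId, conditionId = meta$conditionId)
}

#' Write / read an epoch set as a directory of delimited matrices
#'
#' One `epoch_NNNN.tsv` (samples x channels) per epoch plus
#' `manifest.yaml` with the sampling rate and the per-epoch labels and
#' subject ids.
#'
#' @param epochs an [EpochSet-class].
#' @param dir directory (created if missing).
#' @return `writeEpochSet()` returns `dir` invisibly; `readEpochSet()`
#'   returns an [EpochSet-class].
#' @export
writeEpochSet <- function(epochs, dir) {
  stopifnot(is(epochs, "EpochSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs@epochs)
  for (i in seq_len(d[1])) {
    m <- t(epochs@epochs[i, , , drop = TRUE])
    if (d[2] == 1) m <- matrix(epochs@epochs[i, 1, ], ncol = 1)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(dir, sprintf("epoch_%04d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_yaml(list(fs = epochs@fs, nChannels = d[2], epochSamples = d[3],
                  labels = as.list(epochs@labels),
                  subjectIds = as.list(epochs@subjectIds)),
             file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(dir) {
  meta <- read_yaml(file.path(dir, "manifest.yaml"))
  labels <- as.integer(unlist(meta$labels))
  n <- length(labels)
  arr <- array(0, dim = c(n, meta$nChannels, meta$epochSamples))
  for (i in seq_len(n)) {
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("epoch_%04d.tsv", i)), sep = "\t"))
    arr[i, , ] <- t(m)
  }
  new("EpochSet", epochs = arr, labels = labels,
      subjectIds = as.character(unlist(meta$subjectIds)), fs = meta$fs)
}

#' Write / read a feature matrix as CSV plus manifest
#'
#' `<path>.csv` holds the feature columns with a header row;
#' `<path>_manifest.csv` carries the label, subject id and (optionally) a
#' train/test split flag per row.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path file path without extension.
#' @param trainIdx optional training row indices recorded in the manifest.
#' @return `writeFeatureMatrix()` returns `path` invisibly;
#'   `readFeatureMatrix()` returns a list with `features`
#'   ([FeatureMatrix-class]) and `trainIdx` (or NULL).
#' @export
writeFeatureMatrix <- function(fm, path, trainIdx = NULL) {
  stopifnot(is(fm, "FeatureMatrix"))
  X <- fm@X
  colnames(X) <- fm@columnNames
  utils::write.table(format(X, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(path, ".csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  man <- data.frame(label = fm@y, subject = fm@subjectIds,
                    train = if (is.null(trainIdx)) NA
                            else seq_len(nrow(X)) %in% trainIdx)
  utils::write.csv(man, paste0(path, "_manifest.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  X <- as.matrix(utils::read.csv(paste0(path, ".csv"), check.names = FALSE))
  man <- utils::read.csv(paste0(path, "_manifest.csv"))
  fm <- new("FeatureMatrix", X = unname(X), y = as.integer(man$label),
            subjectIds = as.character(man$subject),
            columnNames = colnames(X))
  trainIdx <- if (all(is.na(man$train))) NULL else which(man$train)
  list(features = fm, trainIdx = trainIdx)
}

#' Serialize / restore a trained DBN as structured text
#'
#' A line-oriented full-precision format: a header, the class labels and
#' standardization vectors, then each RBM layer (unit type, shape, weight
#' rows, biases) and the softmax parameter matrix. Round-trips exactly
#' (`%.17g`).
#'
#' @param model a [DBNModel-class].
#' @param path output file.
#' @return `writeDBNModel()` returns `path` invisibly; `readDBNModel()`
#'   returns the [DBNModel-class].
#' @export
writeDBNModel <- function(model, path) {
  stopifnot(is(model, "DBNModel"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(...), con)
  num <- function(x) paste(fmtNum(x), collapse = " ")
  w("museeg-dbn", "1")
  w("classLabels", paste(model@classLabels, collapse = " "))
  w("center", if (is.null(model@center)) "none" else num(model@center))
  w("scale", if (is.null(model@scale)) "none" else num(model@scale))
  w("nLayers", length(model@rbms))
  for (rbm in model@rbms) {
    w("layer", rbm@unitType, nrow(rbm@W), ncol(rbm@W))
    for (i in seq_len(nrow(rbm@W))) w(num(rbm@W[i, ]))
    w(num(rbm@bVisible))
    w(num(rbm@bHidden))
  }
  w("theta", nrow(model@theta), ncol(model@theta))
  for (i in seq_len(nrow(model@theta))) w(num(model@theta[i, ]))
  invisible(path)
}

#' @rdname writeDBNModel
#' @export
readDBNModel <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  nxt <- function() { l <- lines[pos]; pos <<- pos + 1L; l }
  nums <- function(l) as.numeric(strsplit(trimws(l), " +")[[1]])
  hdr <- strsplit(nxt(), " ")[[1]]
  if (hdr[1] != "museeg-dbn") stop("not a museeg model file", call. = FALSE)
  labels <- as.integer(strsplit(nxt(), " ")[[1]][-1])
  cLine <- sub("^center ", "", nxt())
  center <- if (cLine == "none") NULL else nums(cLine)
  sLine <- sub("^scale ", "", nxt())
  scale <- if (sLine == "none") NULL else nums(sLine)
  nL <- as.integer(strsplit(nxt(), " ")[[1]][2])
  rbms <- vector("list", nL)
  for (l in seq_len(nL)) {
    meta <- strsplit(nxt(), " ")[[1]]
    nh <- as.integer(meta[3]); nv <- as.integer(meta[4])
    W <- matrix(0, nh, nv)
    for (i in seq_len(nh)) W[i, ] <- nums(nxt())
    bV <- nums(nxt()); bH <- nums(nxt())
    rbms[[l]] <- new("RBMParams", W = W, bVisible = bV, bHidden = bH,
                     unitType = meta[2])
  }
  meta <- strsplit(nxt(), " ")[[1]]
  k <- as.integer(meta[2]); d <- as.integer(meta[3])
  theta <- matrix(0, k, d)
  for (i in seq_len(k)) theta[i, ] <- nums(nxt())
  new("DBNModel", rbms = rbms, theta = theta, classLabels = labels,
      center = center, scale = scale)
}
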