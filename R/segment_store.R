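# Domain types for paired scalp/intracranial EEG segments and cohort storage.
#
# A paired segment is the atomic training/evaluation unit: a time-aligned
# scalp window X (L x M) and intracranial window Y (L x Mbar) with an
# IED/non-IED label. Amplitudes are stored normalized to [-1, 1] (the
# generator's tanh output range); time is axis 1 of each matrix, sensors
# axis 2.

#' Construct a scalp EEG segment
#'
#' @param samples numeric matrix, `L` time samples by `M` sensors, amplitudes
#'   in `[-1, 1]`
#' @param sampling_rate sampling rate in Hz
#' @param onset_index sample index of the IED onset within the window, or
#'   `NULL` for non-IED segments
#' @return an object of class `scalp_segment`
#' @export
scalp_segment <- function(samples, sampling_rate = 200, onset_index = NULL) {
  samples <- as.matrix(samples)
  if (!all(is.finite(samples))) stop("scalp segment contains non-finite values")
  if (max(abs(samples)) > 1 + 1e-8)
    stop("scalp segment amplitudes exceed [-1, 1]; normalize before constructing")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 onset_index = onset_index),
            class = "scalp_segment")
}

#' Construct an intracranial EEG segment
#'
#' @param samples numeric matrix, `L` time samples by `Mbar` sensors
#' @param provenance `"real"` for recorded signals, `"estimated"` for
#'   generator output
#' @return an object of class `intracranial_segment`
#' @export
intracranial_segment <- function(samples, provenance = c("real", "estimated")) {
  samples <- as.matrix(samples)
  provenance <- match.arg(provenance)
  if (!all(is.finite(samples))) stop("intracranial segment contains non-finite values")
  if (max(abs(samples)) > 1 + 1e-8)
    stop("intracranial segment amplitudes exceed [-1, 1]")
  structure(list(samples = samples, provenance = provenance),
            class = "intracranial_segment")
}

#' Pair a scalp and an intracranial segment
#'
#' @param scalp a [scalp_segment()]
#' @param intracranial an [intracranial_segment()]
#' @param label `"IED"` or `"nonIED"`
#' @param subject_id subject identifier
#' @return an object of class `paired_segment`
#' @export
paired_segment <- function(scalp, intracranial, label = c("IED", "nonIED"),
                           subject_id = "S1") {
  label <- match.arg(label)
  stopifnot(inherits(scalp, "scalp_segment"),
            inherits(intracranial, "intracranial_segment"))
  if (nrow(scalp$samples) != nrow(intracranial$samples))
    stop("scalp and intracranial segments are not time-aligned: L = ",
         nrow(scalp$samples), " vs ", nrow(intracranial$samples))
  structure(list(scalp = scalp, intracranial = intracranial, label = label,
                 subject_id = subject_id),
            class = "paired_segment")
}

#' Build a subject record from paired segments
#'
#' @param subject_id subject identifier
#' @param segments list of [paired_segment()]s belonging to this subject
#' @param n_ied_total,n_ied_visible optional IED annotation counts (total and
#'   scalp-visible)
#' @return an object of class `subject_record`
#' @export
subject_record <- function(subject_id, segments, n_ied_total = NA_real_,
                           n_ied_visible = NA_real_) {
  ok <- vapply(segments, function(s) identical(s$subject_id, subject_id), logical(1))
  if (!all(ok))
    stop("segments ", paste(which(!ok), collapse = ", "),
         " do not belong to subject ", subject_id)
  structure(list(subject_id = subject_id, segments = segments,
                 n_ied_total = n_ied_total, n_ied_visible = n_ied_visible),
            class = "subject_record")
}

#' Assemble subject records into a cohort
#'
#' @param subjects list of [subject_record()]s with unique subject ids
#' @return an object of class `subject_cohort`
#' @export
subject_cohort <- function(subjects = list()) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(subjects = subjects), class = "subject_cohort")
}

#' @export
print.subject_cohort <- function(x, ...) {
  ns <- length(x$subjects)
  nseg <- sum(vapply(x$subjects, function(s) length(s$segments), numeric(1)))
  cat("subject_cohort:", ns, "subject(s),", nseg, "paired segment(s)\n")
  for (s in x$subjects) {
    labs <- vapply(s$segments, function(p) p$label, character(1))
    cat("  ", s$subject_id, ": ", length(s$segments), " segments (",
        sum(labs == "IED"), " IED)\n", sep = "")
  }
  invisible(x)
}

# stack a subject's segments into arrays (n, L, M) / (n, L, Mbar) / labels
segments_to_arrays <- function(segments) {
  n <- length(segments)
  if (n == 0) return(list(scalp = NULL, intracranial = NULL, labels = character(0)))
  L <- nrow(segments[[1]]$scalp$samples)
  M <- ncol(segments[[1]]$scalp$samples)
  Mb <- ncol(segments[[1]]$intracranial$samples)
  sc <- array(0, c(n, L, M))
  ic <- array(0, c(n, L, Mb))
  for (i in seq_len(n)) {
    si <- segments[[i]]
    if (!identical(dim(si$scalp$samples), c(L, M)) ||
        !identical(dim(si$intracranial$samples), c(L, Mb)))
      stop("segment ", i, " has inconsistent shape")
    sc[i, , ] <- si$scalp$samples
    ic[i, , ] <- si$intracranial$samples
  }
  list(scalp = sc, intracranial = ic,
       labels = vapply(segments, function(s) s$label, character(1)),
       sampling_rate = segments[[1]]$scalp$sampling_rate)
}

arrays_to_segments <- function(scalp, intracranial, labels, subject_id,
                               sampling_rate = 200) {
  n <- dim(scalp)[1]
  lapply(seq_len(n), function(i) {
    paired_segment(
      scalp_segment(matrix(scalp[i, , ], dim(scalp)[2], dim(scalp)[3]),
                    sampling_rate = sampling_rate),
      intracranial_segment(matrix(intracranial[i, , ], dim(intracranial)[2],
                                  dim(intracranial)[3])),
      label = labels[i], subject_id = subject_id)
  })
}

#' Write a cohort to disk
#'
#' The NPZ layout holds, per subject `i` (0-based order of the cohort list),
#' members `s<i>_scalp` (n, L, M), `s<i>_intracranial` (n, L, Mbar),
#' `s<i>_labels` (n; 1 = IED), `s<i>_counts` (total, scalp-visible annotation
#' counts) and `s<i>_rate`; `subject_ids` is a JSON member. Arrays round-trip
#' bit-exactly. The RDS format serializes the cohort object directly.
#'
#' @param cohort a [subject_cohort()]
#' @param path output file path
#' @param format `"npz"` or `"rds"`
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path, format = c("npz", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "subject_cohort"))
  if (format == "rds") {
    saveRDS(cohort, path)
    return(invisible(path))
  }
  out <- list(n_subjects = length(cohort$subjects))
  ids <- character(0)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    arr <- tryCatch(segments_to_arrays(s$segments),
                    error = function(e) stop("subject ", s$subject_id, ": ",
                                             conditionMessage(e)))
    key <- paste0("s", i - 1L)
    if (length(s$segments)) {
      out[[paste0(key, "_scalp")]] <- arr$scalp
      out[[paste0(key, "_intracranial")]] <- arr$intracranial
      out[[paste0(key, "_labels")]] <- as.numeric(arr$labels == "IED")
      out[[paste0(key, "_rate")]] <- arr$sampling_rate
    } else {
      out[[paste0(key, "_rate")]] <- 200
    }
    out[[paste0(key, "_counts")]] <- c(s$n_ied_total, s$n_ied_visible)
    ids <- c(ids, s$subject_id)
  }
  out$subject_ids.json <- charToRaw(jsonlite::toJSON(ids))
  extra <- attr(cohort, "extra_metadata")
  if (!is.null(extra)) for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  npz_write(out, path)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Unrecognized members are preserved in the `extra_metadata` attribute of the
#' returned cohort.
#'
#' @param path cohort file path
#' @param format `"auto"` detects RDS vs NPZ from the file magic
#' @return a [subject_cohort()]
#' @export
read_cohort <- function(path, format = c("auto", "npz", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such cohort file: ", path)
  if (format == "auto") {
    magic <- readBin(path, raw(), 2)
    format <- if (identical(magic, charToRaw("PK"))) "npz" else "rds"
  }
  if (format == "rds") {
    cohort <- readRDS(path)
    stopifnot(inherits(cohort, "subject_cohort"))
    return(cohort)
  }
  d <- npz_read(path)
  ns <- as.integer(d$n_subjects)
  if (is.null(ns)) stop("not a cohort archive (missing n_subjects): ", path)
  ids <- if (!is.null(d$subject_ids.json))
    jsonlite::fromJSON(rawToChar(d$subject_ids.json))
  else paste0("S", seq_len(ns))
  known <- "n_subjects"
  subjects <- vector("list", ns)
  for (i in seq_len(ns)) {
    key <- paste0("s", i - 1L)
    sc <- d[[paste0(key, "_scalp")]]
    ic <- d[[paste0(key, "_intracranial")]]
    lb <- d[[paste0(key, "_labels")]]
    rate <- d[[paste0(key, "_rate")]]
    cnt <- d[[paste0(key, "_counts")]]
    known <- c(known, paste0(key, c("_scalp", "_intracranial", "_labels",
                                    "_rate", "_counts")))
    segs <- list()
    if (!is.null(sc)) {
      if (is.null(ic) || dim(sc)[2] != dim(ic)[2])
        stop("subject ", ids[i], ": scalp and intracranial segment lengths ",
             "are misaligned (L = ", dim(sc)[2], " vs ",
             if (is.null(ic)) "missing" else dim(ic)[2], ")")
      labels <- ifelse(lb > 0.5, "IED", "nonIED")
      segs <- arrays_to_segments(sc, ic, labels, ids[i], rate)
    }
    subjects[[i]] <- subject_record(ids[i], segs,
                                    n_ied_total = cnt[1], n_ied_visible = cnt[2])
  }
  cohort <- subject_cohort(subjects)
  extra <- d[setdiff(names(d), c(known, "subject_ids.json"))]
  if (length(extra)) attr(cohort, "extra_metadata") <- extra
  cohort
}
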