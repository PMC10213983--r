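# Recording and annotation I/O plus the standard preparation rules:
# stage relabeling to the five AASM classes, exclusion of movement/unknown
# epochs, trimming of long wake runs outside the sleep period, rate
# harmonization, and a versioned binary epoch store.

pad_str <- function(s, n) {
  s <- substr(s, 1, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

#' Write waveforms to an EDF file
#'
#' Minimal European Data Format writer (16-bit samples, one fixed-length
#' data record per `record_seconds`).  Physical scaling is chosen per signal
#' from its range, so a round trip reproduces each waveform to within
#' 16-bit quantization of its amplitude span.
#'
#' @param signals Named list of numeric waveforms.
#' @param rates Named sampling rates (Hz); `rate * record_seconds` must be a
#'   whole number of samples and all signals must span the same duration.
#' @param path Output file path.
#' @param record_seconds Data-record duration (s).
#' @return `path`, invisibly.
#' @export
writeEdf <- function(signals, rates, path, record_seconds = 1) {
  stopifnot(length(signals) >= 1, all(names(signals) %in% names(rates)))
  ns <- length(signals)
  spr <- vapply(names(signals), function(m) {
    v <- rates[[m]] * record_seconds
    if (abs(v - round(v)) > 1e-9) stop("rate * record_seconds must be integer")
    as.integer(round(v))
  }, integer(1))
  n_rec <- unique(vapply(seq_len(ns),
                         function(i) length(signals[[i]]) / spr[i], numeric(1)))
  if (length(n_rec) != 1 || abs(n_rec - round(n_rec)) > 1e-9)
    stop("signals must span an integer, common number of data records")
  n_rec <- as.integer(round(n_rec))

  pmin_ <- pmax_ <- numeric(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }
    pmin_[i] <- lo; pmax_[i] <- hi
    dig[[i]] <- as.integer(round((x - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, n) writeChar(pad_str(s, n), con, n, eos = NULL)
  wchar("0", 8)
  wchar("synthetic subject", 80)
  wchar("sleepExit recording", 80)
  wchar("01.01.00", 8)
  wchar("00.00.00", 8)
  wchar(as.character(256 * (ns + 1)), 8)
  wchar("", 44)
  wchar(as.character(n_rec), 8)
  wchar(format(record_seconds), 8)
  wchar(as.character(ns), 4)
  for (i in seq_len(ns)) wchar(names(signals)[i], 16)
  for (i in seq_len(ns)) wchar("", 80)
  for (i in seq_len(ns)) wchar("uV", 8)
  for (i in seq_len(ns)) wchar(format(pmin_[i], digits = 7), 8)
  for (i in seq_len(ns)) wchar(format(pmax_[i], digits = 7), 8)
  for (i in seq_len(ns)) wchar("-32768", 8)
  for (i in seq_len(ns)) wchar("32767", 8)
  for (i in seq_len(ns)) wchar("", 80)
  for (i in seq_len(ns)) wchar(as.character(spr[i]), 8)
  for (i in seq_len(ns)) wchar("", 32)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- dig[[i]][(r - 1) * spr[i] + seq_len(spr[i])]
      writeBin(seg, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param channels Optional channel labels to keep (error, naming the
#'   available channels, if one is absent).
#' @return List with `signals` (named numeric waveforms, physical units),
#'   `rates` (Hz), and `header` (record count and duration).
#' @export
readEdf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rstr <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rstr(8); rstr(80); rstr(80); rstr(8); rstr(8)
  rstr(8); rstr(44)
  n_rec <- as.integer(rstr(8))
  rec_dur <- as.numeric(rstr(8))
  ns <- as.integer(rstr(4))
  labels <- vapply(seq_len(ns), function(i) rstr(16), character(1))
  for (i in seq_len(ns)) rstr(80)
  for (i in seq_len(ns)) rstr(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rstr(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rstr(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rstr(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rstr(8)), numeric(1))
  for (i in seq_len(ns)) rstr(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rstr(8)), integer(1))
  for (i in seq_len(ns)) rstr(32)

  raw_sig <- lapply(seq_len(ns), function(i) integer(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      if (length(seg) < spr[i]) stop("truncated EDF data")
      raw_sig[[i]][(r - 1) * spr[i] + seq_len(spr[i])] <- seg
    }
  }
  signals <- lapply(seq_len(ns), function(i) {
    (raw_sig[[i]] - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) +
      pmin_[i]
  })
  names(signals) <- labels
  rates <- spr / rec_dur
  names(rates) <- labels
  if (!is.null(channels)) {
    missing <- setdiff(channels, labels)
    if (length(missing) > 0)
      stop("channel(s) ", paste(missing, collapse = ", "),
           " not in file; available: ", paste(labels, collapse = ", "))
    signals <- signals[channels]
    rates <- rates[channels]
  }
  list(signals = signals, rates = rates,
       header = list(n_records = n_rec, record_seconds = rec_dur))
}

#' Read a recording through a manifest entry
#'
#' @param edf_path EDF file path.
#' @param manifest_entry List with a `channels` element mapping modality
#'   names to channel labels, e.g.
#'   `list(channels = c(eeg = "EEG Fpz-Cz", eog = "EOG horizontal"))`.
#' @return List with per-modality `signals` and `rates`.
#' @export
readRecording <- function(edf_path, manifest_entry) {
  ch <- manifest_entry$channels
  ed <- readEdf(edf_path, channels = unname(ch))
  signals <- ed$signals[unname(ch)]
  names(signals) <- names(ch)
  rates <- ed$rates[unname(ch)]
  names(rates) <- names(ch)
  list(signals = signals, rates = rates)
}

#' Resample waveforms to a common rate
#'
#' Polyphase resampling of every modality to `target_rate`; output lengths
#' are equalized to `round(duration * target_rate)`.
#'
#' @param signals Named list of waveforms.
#' @param rates Named sampling rates (Hz).
#' @param target_rate Target rate (Hz).
#' @return List with resampled `signals` and updated `rates`.
#' @export
harmonizeRates <- function(signals, rates, target_rate) {
  stopifnot(target_rate > 0)
  out <- signals
  for (m in names(signals)) {
    r <- rates[[m]]
    n_out <- round(length(signals[[m]]) / r * target_rate)
    if (abs(r - target_rate) < 1e-9) next
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    p <- round(target_rate * 1000); q <- round(r * 1000)
    cd <- g(p, q)
    y <- signal::resample(signals[[m]], p / cd, q / cd)
    if (length(y) >= n_out) y <- y[seq_len(n_out)]
    else y <- c(y, rep(y[length(y)], n_out - length(y)))
    out[[m]] <- as.numeric(y)
  }
  list(signals = out, rates = stats::setNames(rep(target_rate, length(out)),
                                              names(out)))
}

.rk_levels <- c("W", "WAKE", "N1", "N2", "N3", "N4", "REM", "MOVEMENT",
                "UNKNOWN")

#' Relabel R&K hypnogram labels to the five AASM classes
#'
#' N4 is merged into N3; MOVEMENT and UNKNOWN epochs are flagged for
#' exclusion; W/WAKE, N1, N2, N3 and REM pass through.
#'
#' @param labels Character vector of per-epoch labels.
#' @return List with `labels` (AASM labels, `NA` at excluded epochs) and
#'   `keep` (logical mask).
#' @export
relabelAasm <- function(labels) {
  labels <- toupper(as.character(labels))
  bad <- setdiff(unique(labels), .rk_levels)
  if (length(bad) > 0)
    stop("unknown hypnogram label(s): ", paste(bad, collapse = ", "))
  out <- labels
  out[labels == "WAKE"] <- "W"
  out[labels == "N4"] <- "N3"
  keep <- !(labels %in% c("MOVEMENT", "UNKNOWN"))
  out[!keep] <- NA_character_
  list(labels = out, keep = keep)
}

#' Trim long wake runs outside the sleep period
#'
#' Keeps at most `max_lead_min` minutes of continuous wake immediately
#' before the first and after the last non-wake epoch; interior wake is
#' never touched.  An all-wake record keeps its final `max_lead_min`
#' minutes, with a warning.
#'
#' @param labels Character vector of AASM labels (`NA` allowed; counted as
#'   non-wake for run purposes only if non-`NA` — excluded epochs keep their
#'   own mask).
#' @param epoch_seconds Epoch duration (s); must divide the trim window.
#' @param max_lead_min Wake minutes retained on each side (default 30).
#' @return Logical keep-mask of the same length.
#' @export
trimWake <- function(labels, epoch_seconds = 30, max_lead_min = 30) {
  max_lead <- (max_lead_min * 60) %/% epoch_seconds
  if ((max_lead_min * 60) %% epoch_seconds != 0)
    stop("epoch duration must divide the trim window")
  n <- length(labels)
  keep <- rep(TRUE, n)
  is_sleep <- !is.na(labels) & labels != "W"
  if (!any(is_sleep)) {
    warning("all-wake record: keeping only the final ", max_lead_min,
            " minutes")
    keep[] <- FALSE
    keep[max(1, n - max_lead + 1):n] <- TRUE
    return(keep)
  }
  first_s <- which(is_sleep)[1]
  last_s <- which(is_sleep)[sum(is_sleep)]
  if (first_s - 1 > max_lead) keep[seq_len(first_s - 1 - max_lead)] <- FALSE
  n_trail <- n - last_s
  if (n_trail > max_lead) keep[(last_s + max_lead + 1):n] <- FALSE
  keep
}

#' Read a hypnogram from a two-column CSV
#'
#' Expected columns: `epoch_index` (0- or 1-based, monotone) and `label`.
#'
#' @param path CSV file path.
#' @return Character vector of labels in epoch order.
#' @export
readHypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "label") %in% names(df)))
    stop("hypnogram CSV needs columns epoch_index,label")
  df$label[order(df$epoch_index)]
}

#' Cut a recording into labeled 30-s epochs
#'
#' Applies the fixed preparation order — relabel to AASM, trim wake, epoch
#' extraction — to one recording plus its hypnogram.  Epochs are cut from
#' annotation boundaries as 0-based half-open intervals after rate
#' harmonization.
#'
#' @param recording List with `signals` and `rates` (see [readRecording()]).
#' @param hypnogram Character vector of per-epoch R&K or AASM labels.
#' @param target_rate Common grid rate (Hz).
#' @param epoch_seconds Epoch duration (s).
#' @param subject Subject identifier stored per epoch.
#' @return An [EpochSet-class] of the kept epochs.
#' @export
epochsFromRecording <- function(recording, hypnogram, target_rate = 100,
                                epoch_seconds = 30, subject = "S1") {
  harm <- harmonizeRates(recording$signals, recording$rates, target_rate)
  rel <- relabelAasm(hypnogram)
  keep <- rel$keep & trimWake(rel$labels, epoch_seconds)
  npts <- round(epoch_seconds * target_rate)
  n_avail <- min(vapply(harm$signals, length, numeric(1))) %/% npts
  idx <- which(keep & seq_along(hypnogram) <= n_avail)
  if (length(idx) == 0) stop("no epochs left after preparation")
  mats <- lapply(harm$signals, function(x) {
    vapply(idx, function(i) x[(i - 1) * npts + seq_len(npts)], numeric(npts))
  })
  EpochSet(mats, stage = rel$labels[idx], sampleRate = target_rate,
           epochSeconds = epoch_seconds,
           subject = rep(subject, length(idx)))
}

## ---- epoch store -----------------------------------------------------------

.store_magic <- "SLEEPEPOCHSTORE1"
.store_version <- 1L

#' Write an EpochSet to the binary epoch store
#'
#' Versioned container: a magic string and version, the sampling grid, the
#' modality names, per-epoch stage/tier/subject annotations, then the raw
#' double-precision waveform matrices.  Round-trips bitwise.
#'
#' @param es An [EpochSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEpochStore <- function(es, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wstr <- function(s) {
    r <- charToRaw(s)
    writeBin(length(r), con)
    writeBin(r, con)
  }
  writeChar(.store_magic, con, nchar(.store_magic), eos = NULL)
  writeBin(.store_version, con)
  writeBin(as.double(sampleRate(es)), con)
  writeBin(as.double(es@epochSeconds), con)
  mods <- modalities(es)
  writeBin(length(mods), con)
  for (m in mods) wstr(m)
  n <- ncol(es)
  writeBin(n, con)
  writeBin(nrow(assay(es, 1)), con)
  writeBin(as.integer(stages(es)), con)
  tr <- tiers(es)
  writeBin(as.integer(!is.null(tr)), con)
  if (!is.null(tr)) for (s in tr) wstr(s)
  su <- subjects(es)
  writeBin(as.integer(!is.null(su)), con)
  if (!is.null(su)) for (s in su) wstr(s)
  for (m in mods) writeBin(as.vector(assay(es, m)), con)
  invisible(path)
}

#' Read an EpochSet from the binary epoch store
#'
#' @param path Store path written by [writeEpochStore()].
#' @return An [EpochSet-class].
#' @export
readEpochStore <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rstr <- function() {
    nc <- readBin(con, "integer")
    if (length(nc) == 0) stop("truncated epoch store")
    rawToChar(readBin(con, "raw", nc))
  }
  magic <- readChar(con, nchar(.store_magic), useBytes = TRUE)
  if (!identical(magic, .store_magic)) stop("not an epoch store file")
  ver <- readBin(con, "integer")
  if (!identical(ver, .store_version))
    stop("epoch store version ", ver, " not supported (expected ",
         .store_version, ")")
  rate <- readBin(con, "double")
  dur <- readBin(con, "double")
  n_mod <- readBin(con, "integer")
  mods <- vapply(seq_len(n_mod), function(i) rstr(), character(1))
  n <- readBin(con, "integer")
  npts <- readBin(con, "integer")
  stage_i <- readBin(con, "integer", n)
  if (length(stage_i) < n) stop("truncated epoch store")
  has_tier <- readBin(con, "integer")
  tr <- if (has_tier == 1)
    vapply(seq_len(n), function(i) rstr(), character(1)) else NULL
  has_subj <- readBin(con, "integer")
  su <- if (has_subj == 1)
    vapply(seq_len(n), function(i) rstr(), character(1)) else NULL
  mats <- list()
  for (m in mods) {
    v <- readBin(con, "double", npts * n)
    if (length(v) < npts * n) stop("truncated epoch store")
    mats[[m]] <- matrix(v, npts, n)
  }
  EpochSet(mats, stage = SLEEP_STAGES[stage_i], sampleRate = rate,
           epochSeconds = dur, tier = tr, subject = su)
}

#' Subject-wise cross-validation folds
#'
#' Assigns every epoch to one of `k` folds such that no subject appears in
#' more than one fold (the defensible default for evaluating staging models;
#' epoch-wise assignment is available for diagnostics).
#'
#' @param es An [EpochSet-class] with subject annotations.
#' @param k Number of folds.
#' @param by `"subject"` (default) or `"epoch"`.
#' @param seed Seed for the assignment shuffle.
#' @return Integer fold index per epoch.
#' @export
subjectFolds <- function(es, k = 10, by = c("subject", "epoch"), seed = 1L) {
  by <- match.arg(by)
  n <- ncol(es)
  if (by == "epoch")
    return(with_seed(seed, sample(rep_len(seq_len(k), n))))
  su <- subjects(es)
  if (is.null(su)) stop("EpochSet has no subject annotations")
  subs <- unique(su)
  if (length(subs) < k)
    stop("only ", length(subs), " subjects for ", k, " folds")
  fold_of <- with_seed(seed, setNames(sample(rep_len(seq_len(k),
                                                     length(subs))), subs))
  unname(fold_of[su])
}
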