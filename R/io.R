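#' @include AllClasses.R summaries.R
NULL

.fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write an ensemble to CSV with a JSON metadata sidecar
#'
#' Long-format CSV with header
#' `replicate,rank,locus,frequency,generations,metric_at_stop,discarded_burn_ins`
#' (one row per replicate and rank; `locus` is the original locus index
#' holding that rank).  Numbers are written with 17 significant digits so
#' a read/write round trip is bit-exact.  Full parameters, seed and source
#' tag go to `<path>.json`.
#'
#' @param ens an [ArchitectureEnsemble-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [readEnsembleCsv()]
#' @export
writeEnsembleCsv <- function(ens, path) {
  stopifnot(is(ens, "ArchitectureEnsemble"))
  n <- nReplicates(ens)
  L <- ncol(ens@freqs)
  ords <- t(apply(ens@locusFreqs, 1, orderLoci))
  if (L == 1L) ords <- matrix(ords, ncol = 1L)
  lines <- character(n * L + 1L)
  lines[1] <- paste("replicate", "rank", "locus", "frequency",
                    "generations", "metric_at_stop", "discarded_burn_ins",
                    sep = ",")
  i <- 2L
  for (r in seq_len(n)) {
    for (k in seq_len(L)) {
      lines[i] <- paste(r, k, ords[r, k], .fmt17(ens@freqs[r, k]),
                        .fmt17(ens@generations[r]),
                        .fmt17(ens@metricAtStop[r]),
                        ens@discards[r], sep = ",")
      i <- i + 1L
    }
  }
  writeLines(lines, path)
  meta <- list(
    source = ens@source, seed = ens@seed, replicates = n,
    params = list(
      ne = ens@params@ne, num_loci = ens@params@L,
      theta = ens@params@theta, s_b = ens@params@sB, s_d = ens@params@sD,
      delta = ens@params@delta, f_w = ens@params@fW,
      burn_in_factor = ens@params@burnInFactor,
      seed = ens@params@seed, start_mode = ens@params@startMode),
    version = as.character(utils::packageVersion("polysweep")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ensemble written by [writeEnsembleCsv()]
#'
#' @param path CSV path; `<path>.json` must exist alongside.
#' @return an [ArchitectureEnsemble-class], bit-identical to the one
#'   written.
#' @export
readEnsembleCsv <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(
    replicate = "integer", rank = "integer", locus = "integer",
    frequency = "numeric", generations = "numeric",
    metric_at_stop = "numeric", discarded_burn_ins = "integer"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- max(tab$replicate)
  L <- max(tab$rank)
  freqs <- matrix(NA_real_, n, L)
  locusF <- matrix(NA_real_, n, L)
  freqs[cbind(tab$replicate, tab$rank)] <- tab$frequency
  locusF[cbind(tab$replicate, tab$locus)] <- tab$frequency
  colnames(freqs) <- c("major", if (L > 1) paste0("minor", seq_len(L - 1)))
  colnames(locusF) <- paste0("locus", seq_len(L))
  one <- tab[tab$rank == 1L, ]
  one <- one[order(one$replicate), ]
  pm <- meta$params
  params <- modelParams(
    ne = pm$ne, L = pm$num_loci, theta = pm$theta, sB = pm$s_b,
    sD = pm$s_d, delta = pm$delta, fW = pm$f_w,
    burnInFactor = pm$burn_in_factor, seed = pm$seed,
    startMode = pm$start_mode)
  new("ArchitectureEnsemble",
      freqs = freqs, locusFreqs = locusF,
      generations = one$generations,
      metricAtStop = one$metric_at_stop,
      discards = one$discarded_burn_ins,
      params = params, source = meta$source,
      seed = as.integer(meta$seed))
}
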