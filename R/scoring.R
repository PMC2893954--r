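#' Per-plate z-scores
#'
#' Standardizes each well of a plate as z = (x - mu) / sigma, where mu and
#' sigma are the mean and sample standard deviation (n - 1) of the percent
#' GFP-positive values over all sample wells of that plate, excluding
#' controls. Control wells still receive z values (for QC) but never
#' contribute to mu or sigma.
#'
#' @param readout a \linkS4class{PlateReadout}.
#' @return list with \code{z} (named numeric over all measured wells) and
#'   \code{stats} (list mu, sigma, nIncluded).
#' @examples
#' layout <- defaultControlLayout("p1")
#' wells <- wellsWithRole(layout, "sample")[1:5]
#' r <- PlateReadout(layout, stats::setNames(c(2, 4, 6, 8, 10), wells))
#' plateZScores(r)$z[wells[5]] # (10 - 6) / sqrt(10)
#' @export
plateZScores <- function(readout) {
  stopifnot(is(readout, "PlateReadout"))
  v <- wellValues(readout)
  samples <- intersect(names(v), wellsWithRole(readout, "sample"))
  if (length(samples) < 2L)
    stop("degenerate plate '", plateId(readout),
         "': fewer than 2 measured sample wells")
  mu <- mean(v[samples])
  sigma <- stats::sd(v[samples])
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate plate '", plateId(readout),
         "': zero standard deviation over sample wells")
  list(z = (v - mu) / sigma,
       stats = list(mu = mu, sigma = sigma, nIncluded = length(samples)))
}

#' Negative-control-based z-scores
#'
#' Validation-stage standardization: z = (x - mu_neg) / sigma_neg, with
#' mean and sample standard deviation taken over the negative-control
#' (Rluc) wells of the corresponding replicate.
#'
#' @param values numeric vector of per-replicate measurements for one
#'   esiRNA (NA for a missing replicate).
#' @param negControls either a single numeric vector of negative-control
#'   values applied to every replicate, or a list of such vectors, one per
#'   replicate.
#' @param esirna optional esiRNA identifier carried through.
#' @return list with \code{esirna}, \code{z} (per replicate), \code{avgZ},
#'   \code{nReps} (finite replicates used), \code{partial} flag, and
#'   \code{mode} = "negative_control".
#' @export
controlZScores <- function(values, negControls, esirna = NA_character_) {
  if (!is.list(negControls))
    negControls <- rep(list(negControls), length(values))
  if (length(negControls) != length(values))
    stop("need one negative-control vector per replicate")
  z <- vapply(seq_along(values), function(i) {
    nc <- negControls[[i]]
    if (length(nc) < 2L)
      stop("fewer than 2 negative-control values in replicate ", i)
    s <- stats::sd(nc)
    if (!is.finite(s) || s == 0)
      stop("degenerate negative controls in replicate ", i,
           ": zero standard deviation")
    (values[i] - mean(nc)) / s
  }, numeric(1))
  avg <- averageReplicates(z)
  list(esirna = esirna, z = z, avgZ = avg$avgZ, nReps = avg$n,
       partial = avg$n < length(values), mode = "negative_control")
}

#' Average per-replicate z-scores
#'
#' Arithmetic mean over the available (finite) replicate z values; the
#' number of contributing replicates is recorded so partial data are
#' flagged rather than dropped.
#'
#' @param z numeric vector of per-replicate z values (NA allowed).
#' @return list with \code{avgZ} and \code{n}.
#' @export
averageReplicates <- function(z) {
  keep <- is.finite(z)
  if (!any(keep))
    stop("no finite replicate z-scores to average")
  list(avgZ = mean(z[keep]), n = sum(keep))
}

#' Per-esiRNA z-score table across plates and replicates
#'
#' Runs one of the two normalization schemes over a set of plate readouts
#' and summarizes per esiRNA: per-replicate z (plates standardized
#' separately in "plate" mode; against the replicate's pooled
#' negative-control wells in "control" mode), then the replicate average.
#'
#' @param readouts list of \linkS4class{PlateReadout}.
#' @param libraryMap library map data.frame (esirna_id, gene_id,
#'   trigger_index); optional, merged when given.
#' @param mode "plate" (per-plate sample-well mu/sigma) or "control"
#'   (negative-control mu/sigma).
#' @return data.frame: esirna_id, gene_id, trigger_index (when a library
#'   map is given), one z_rep<i> column per replicate, avg_z, n_reps, mode.
#' @export
zScoreTable <- function(readouts, libraryMap = NULL,
                        mode = c("plate", "control")) {
  mode <- match.arg(mode)
  perWell <- do.call(rbind, lapply(readouts, function(r) {
    v <- wellValues(r)
    roles <- wellRoles(r)[names(v)]
    z <- if (mode == "plate") {
      plateZScores(r)$z
    } else {
      neg <- v[roles == "negative_control"]
      if (length(neg) < 2L)
        stop("plate '", plateId(r), "' replicate ", replicateId(r),
             ": fewer than 2 measured negative-control wells")
      s <- stats::sd(neg)
      if (!is.finite(s) || s == 0)
        stop("plate '", plateId(r), "' replicate ", replicateId(r),
             ": degenerate negative controls")
      (v - mean(neg)) / s
    }
    data.frame(esirna_id = wellEsiRNA(r)[names(v)],
               replicate_id = replicateId(r),
               z = as.numeric(z[names(v)]),
               role = roles, stringsAsFactors = FALSE)
  }))
  perWell <- perWell[!is.na(perWell$esirna_id) & perWell$role == "sample", ]
  reps <- sort(unique(perWell$replicate_id))
  ids <- unique(perWell$esirna_id)
  zmat <- matrix(NA_real_, length(ids), length(reps),
                 dimnames = list(ids, paste0("z_rep", reps)))
  for (j in seq_along(reps)) {
    chunk <- perWell[perWell$replicate_id == reps[j], ]
    agg <- tapply(chunk$z, chunk$esirna_id, mean)
    zmat[names(agg), j] <- agg
  }
  avg <- apply(zmat, 1L, function(z) unlist(averageReplicates(z)))
  out <- data.frame(esirna_id = ids, zmat,
                    avg_z = avg["avgZ", ], n_reps = as.integer(avg["n", ]),
                    mode = if (mode == "plate") "plate_samples"
                           else "negative_control",
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(libraryMap))
    out <- merge(libraryMap, out, by = "esirna_id", sort = FALSE)
  out
}
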