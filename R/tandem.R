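#' Self-dotplot of a sequence
#'
#' Window-vs-window self comparison: a point (i, j), i < j, is emitted
#' when the two windows agree at \code{min_identity} or better. Only the
#' upper triangle is stored and the main diagonal is excluded; parallel
#' off-diagonals at spacings of the monomer length are the classic
#' signature of a tandem repeat.
#'
#' @param sequence character scalar (or \code{consensus_seq}).
#' @param window window length in bp (default 20).
#' @param min_identity window match threshold (default 0.8).
#' @param step window start stride (1 = every position).
#' @return a \code{self_dotplot}: data.frame with \code{i}, \code{j}
#'   (1-based window starts) and \code{identity}; attributes
#'   \code{window}, \code{length}.
#' @export
self_dotplot <- function(sequence, window = 20L, min_identity = 0.8,
                         step = 1L) {
  if (inherits(sequence, "consensus_seq")) sequence <- sequence$sequence
  L <- nchar(sequence)
  if (2L * window > L) stop("window longer than half the sequence")
  df <- dotplot_cpp(toupper(sequence), as.integer(window), min_identity,
                    as.integer(step))
  structure(df, class = c("self_dotplot", "data.frame"),
            window = as.integer(window), length = L)
}

#' Detect tandem periodicity, monomer length and higher-order structure
#'
#' Computes the lag-identity profile identity(lag) = matches(s[i],
#' s[i+lag]) / (L - lag) -- the quantitative analogue of self-dotplot
#' diagonal spacing -- and calls:
#' \itemize{
#'   \item \code{fundamental_period}: the smallest local-maximum lag with
#'     identity >= \code{t_fund};
#'   \item \code{hor_period}: the smallest lag beyond the fundamental
#'     with identity >= \code{t_hor} at an integer multiple (+/- 1 bp)
#'     of the fundamental, reported only when the fundamental itself
#'     stays below \code{t_hor} -- the signature of a higher-order
#'     repeat whose unit is built from diverged copies of the monomer
#'     (e.g. a 232 bp dimer of two related 116 bp monomers).
#' }
#' Classification is \code{"none"} (no fundamental),
#' \code{"simple_tandem"}, or \code{"higher_order"}.
#'
#' @param sequence character scalar (or \code{consensus_seq}).
#' @param min_lag,max_lag lag range searched (bp); \code{max_lag} is
#'   clamped to half the sequence length.
#' @param t_fund identity threshold for the fundamental period (0.70
#'   keeps ~15\%-diverged monomers above threshold).
#' @param t_hor identity threshold separating the homogeneous HOR period
#'   from the diverged fundamental (0.95).
#' @return a \code{monomer_call}: list with \code{fundamental_period},
#'   \code{hor_period}, \code{fundamental_identity}, \code{hor_identity},
#'   \code{classification}, \code{profile} (data.frame lag/identity).
#' @export
detect_periodicity <- function(sequence, min_lag = 5L, max_lag = 2000L,
                               t_fund = 0.70, t_hor = 0.95) {
  if (inherits(sequence, "consensus_seq")) sequence <- sequence$sequence
  L <- nchar(sequence)
  max_lag <- min(as.integer(max_lag), L %/% 2L)
  out_none <- structure(list(fundamental_period = NA_integer_,
                             hor_period = NA_integer_,
                             fundamental_identity = NA_real_,
                             hor_identity = NA_real_,
                             classification = "none",
                             profile = NULL),
                        class = "monomer_call")
  if (max_lag < min_lag) return(out_none)
  idv <- lag_identity_cpp(toupper(sequence), as.integer(min_lag), max_lag)
  lags <- seq.int(min_lag, max_lag)
  prof <- data.frame(lag = lags, identity = idv)
  n <- length(idv)
  if (n == 0) return(out_none)
  left <- c(-Inf, idv[-n])
  right <- c(idv[-1], -Inf)
  is_max <- idv >= left & idv >= right
  cand <- which(is_max & idv >= t_fund)
  if (!length(cand)) { out_none$profile <- prof; return(out_none) }
  fi <- cand[1]
  fund <- lags[fi]
  fund_id <- idv[fi]
  if (fund_id >= t_hor) {
    return(structure(list(fundamental_period = fund, hor_period = NA_integer_,
                          fundamental_identity = fund_id,
                          hor_identity = NA_real_,
                          classification = "simple_tandem", profile = prof),
                     class = "monomer_call"))
  }
  hor <- NA_integer_; hor_id <- NA_real_
  for (j in seq_along(lags)) {
    lag <- lags[j]
    if (lag <= fund) next
    if (idv[j] < t_hor || !is_max[j]) next
    m <- round(lag / fund)
    if (m >= 2 && abs(lag - m * fund) <= 1) { hor <- lag; hor_id <- idv[j]; break }
  }
  structure(list(fundamental_period = fund, hor_period = hor,
                 fundamental_identity = fund_id, hor_identity = hor_id,
                 classification = if (is.na(hor)) "simple_tandem"
                                  else "higher_order",
                 profile = prof),
            class = "monomer_call")
}

#' @export
print.monomer_call <- function(x, ...) {
  cat(sprintf("monomer_call: %s (fundamental %s bp, HOR %s bp)\n",
              x$classification,
              ifelse(is.na(x$fundamental_period), "-", x$fundamental_period),
              ifelse(is.na(x$hor_period), "-", x$hor_period)))
  invisible(x)
}

#' Tabulate monomer calls across clusters
#'
#' @param calls named list of \code{monomer_call} (names = cluster ids).
#' @return data.frame sorted by cluster id: \code{cluster},
#'   \code{fundamental}, \code{hor}, \code{classification}.
#' @export
monomer_table <- function(calls) {
  if (!length(calls))
    return(data.frame(cluster = character(), fundamental = integer(),
                      hor = integer(), classification = character(),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    cluster = names(calls),
    fundamental = vapply(calls, function(x)
      as.integer(x$fundamental_period %||% NA_integer_), integer(1)),
    hor = vapply(calls, function(x)
      as.integer(x$hor_period %||% NA_integer_), integer(1)),
    classification = vapply(calls, `[[`, "", "classification"),
    stringsAsFactors = FALSE)
  suppressWarnings({
    num <- as.numeric(df$cluster)
    ord <- if (!anyNA(num)) order(num) else order(df$cluster)
  })
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}
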