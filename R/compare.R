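## Group-level repeat-density comparisons: the per-gene whole-window
## density (bp/Mbp) is the unit of observation, and each expression
## class (Dn, Up) is compared against the neutral class (Nu) with a
## two-sided pooled-variance Student t-test. Welch's unequal-variance
## test is available behind a flag.

#' Split per-gene window densities by expression class
#'
#' Looks up each classified gene's whole-window density and returns one
#' numeric vector per class. Genes classified but absent from the
#' profiles (e.g. dropped for window truncation) are excluded with a
#' warning; classes left with fewer than two genes are dropped with a
#' warning since no comparison is possible for them.
#'
#' @param profiles a [BinProfileSet].
#' @param classification a [GeneClassification].
#' @return named list with (up to) elements `Dn`, `Nu`, `Up`, each a
#'   named numeric vector of densities in bp/Mbp.
#' @export
densitiesByClass <- function(profiles, classification) {
  stopifnot(is(profiles, "BinProfileSet"),
            is(classification, "GeneClassification"))
  dens <- geneWindowDensity(profiles)
  calls <- classCalls(classification)
  missing <- setdiff(names(calls), names(dens))
  if (length(missing))
    warning(length(missing),
            " classified gene(s) lack profiles and were dropped")
  shared <- intersect(names(calls), names(dens))
  out <- split(dens[shared], factor(calls[shared], c("Dn", "Nu", "Up")))
  small <- names(out)[vapply(out, length, 1L) < 2L]
  if (length(small)) {
    warning("class(es) with <2 genes skipped: ",
            paste(small, collapse = ","))
    out <- out[setdiff(names(out), small)]
  }
  out
}

#' Compare a class's densities against the neutral class
#'
#' Two-sided two-sample t-test (pooled-variance Student by default,
#' Welch optionally) of the class densities against the Nu densities.
#' `direction` is `"increased"` when the class mean exceeds the Nu mean,
#' `"reduced"` when below, `"equal"` for an exact tie.
#'
#' @param valuesClass numeric vector of per-gene densities for the class
#'   (>= 2 values).
#' @param valuesNu numeric vector for the neutral genes (>= 2 values).
#' @param base,contrast labels recorded in the output (e.g. `"T"`,
#'   `"Dn-vs-Nu"`).
#' @param welch use Welch's unequal-variance t-test instead of the
#'   pooled test.
#' @return one-row data.frame: base, contrast, n_class, n_nu,
#'   mean_class, mean_nu, t, df, p, direction.
#' @export
compareClasses <- function(valuesClass, valuesNu, base = NA_character_,
                           contrast = NA_character_, welch = FALSE) {
  if (length(valuesClass) < 2L || length(valuesNu) < 2L)
    stop("at least 2 values per side required")
  if (welch) {
    if (stats::sd(valuesClass) == 0 && stats::sd(valuesNu) == 0) {
      d <- mean(valuesClass) - mean(valuesNu)
      r <- list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0,
                df = NA_real_, mean1 = mean(valuesClass),
                mean2 = mean(valuesNu))
    } else {
      tt <- stats::t.test(valuesClass, valuesNu, var.equal = FALSE)
      r <- list(t = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter),
                mean1 = mean(valuesClass), mean2 = mean(valuesNu))
    }
  } else {
    r <- .pooledTVec(valuesClass, valuesNu)
  }
  d <- r$mean1 - r$mean2
  data.frame(base = base, contrast = contrast,
             n_class = length(valuesClass), n_nu = length(valuesNu),
             mean_class = r$mean1, mean_nu = r$mean2,
             t = r$t, df = r$df, p = r$p,
             direction = if (d > 0) "increased"
                         else if (d < 0) "reduced" else "equal",
             stringsAsFactors = FALSE)
}

#' Exploratory per-bin class-vs-Nu comparison
#'
#' Applies the class-vs-Nu t-test bin by bin on per-gene per-bin
#' densities (`1e6 * binBp / coveredBp`). No multiple-testing
#' correction is applied across the bins; this table supports profile
#' plotting and locating where along the window a density difference
#' sits, not confirmatory inference.
#'
#' @param profiles a [BinProfileSet].
#' @param classification a [GeneClassification].
#' @param contrast `"Dn"` or `"Up"` (compared against `"Nu"`).
#' @return data.frame with one row per bin: bin, n_class, n_nu,
#'   mean_class, mean_nu, t, p.
#' @export
perBinComparison <- function(profiles, classification,
                             contrast = c("Dn", "Up")) {
  contrast <- match.arg(contrast)
  stopifnot(is(profiles, "BinProfileSet"),
            is(classification, "GeneClassification"))
  calls <- classCalls(classification)
  ids <- geneIds(profiles)
  shared <- intersect(ids, names(calls))
  cls <- shared[calls[shared] == contrast]
  nu <- shared[calls[shared] == "Nu"]
  if (length(cls) < 2L || length(nu) < 2L)
    stop("need >= 2 genes in both '", contrast, "' and 'Nu'")
  bb <- binBp(profiles); cb <- coveredBp(profiles)
  dens <- matrix(NA_real_, nrow = nrow(bb), ncol = ncol(bb),
                 dimnames = dimnames(bb))
  pos <- cb > 0
  dens[pos] <- 1e6 * bb[pos] / cb[pos]
  nb <- ncol(bb)
  out <- data.frame(bin = seq_len(nb), n_class = NA_integer_,
                    n_nu = NA_integer_, mean_class = NA_real_,
                    mean_nu = NA_real_, t = NA_real_, p = NA_real_)
  for (i in seq_len(nb)) {
    x <- dens[cls, i]; y <- dens[nu, i]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    out$n_class[i] <- length(x); out$n_nu[i] <- length(y)
    if (length(x) < 2L || length(y) < 2L) next
    r <- .pooledTVec(x, y)
    out$mean_class[i] <- r$mean1; out$mean_nu[i] <- r$mean2
    out$t[i] <- r$t; out$p[i] <- r$p
  }
  out
}

#' All class-vs-Nu density comparisons for one experiment
#'
#' Convenience wrapper combining [densitiesByClass()] and
#' [compareClasses()] for the requested contrasts.
#'
#' @param profiles a [BinProfileSet].
#' @param classification a [GeneClassification].
#' @param contrasts classes to compare against Nu.
#' @param welch use Welch's test.
#' @return data.frame, one row per feasible contrast.
#' @export
compareDensities <- function(profiles, classification,
                             contrasts = c("Dn", "Up"), welch = FALSE) {
  byClass <- densitiesByClass(profiles, classification)
  if (!"Nu" %in% names(byClass))
    stop("neutral class unavailable (fewer than 2 Nu genes)")
  rows <- list()
  for (ct in contrasts) {
    if (!ct %in% names(byClass)) next
    rows[[ct]] <- compareClasses(byClass[[ct]], byClass$Nu,
                                 base = profiles@base,
                                 contrast = paste0(ct, "-vs-Nu"),
                                 welch = welch)
  }
  do.call(rbind, rows)
}
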