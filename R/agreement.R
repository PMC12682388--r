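#' Build a paired 2x2 contingency table
#'
#' Cross-tabulates paired binary calls (AI vs reference reader, or exposure
#' vs outcome): `a` both positive, `b` first-only positive, `c` second-only
#' positive, `d` both negative.
#'
#' @param calls_ai Logical vector (rows: AI call / exposure).
#' @param calls_ref Logical vector of equal length, same unit ordering
#'   (columns: reference call / outcome).
#' @return An object of class `"table2x2"`.
#' @export
build_contingency <- function(calls_ai, calls_ref) {
  if (length(calls_ai) != length(calls_ref))
    stop("paired call vectors differ in length")
  if (anyNA(calls_ai) || anyNA(calls_ref))
    stop("paired calls must not contain missing entries")
  calls_ai <- as.logical(calls_ai); calls_ref <- as.logical(calls_ref)
  table2x2(a = sum(calls_ai & calls_ref),
           b = sum(calls_ai & !calls_ref),
           c = sum(!calls_ai & calls_ref),
           d = sum(!calls_ai & !calls_ref))
}

#' @rdname build_contingency
#' @param a,b,c,d Cell counts (both-positive, first-only, second-only,
#'   both-negative).
#' @export
table2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(as.list(c(counts, n = sum(counts))), class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(rows = c("+", "-"), cols = c("+", "-")))
  print(m)
  invisible(x)
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement kappa = (po - pe) / (1 - pe) for a paired 2x2
#' table, with the Fleiss-Cohen-Everitt large-sample standard error and a
#' normal-approximation confidence interval.
#'
#' @param tab A [table2x2()].
#' @param conf Confidence level (default 0.95).
#' @return An object of class `"kappa_result"`: list with `kappa`, `se`,
#'   `ci95` (length-2 numeric), `po`, `pe`, `n`.
#' @export
cohen_kappa <- function(tab, conf = 0.95) {
  stopifnot(inherits(tab, "table2x2"))
  n <- tab$n
  p <- matrix(c(tab$a, tab$b, tab$c, tab$d), 2, 2, byrow = TRUE) / n
  pi_ <- rowSums(p); pj_ <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pi_ * pj_)
  if (1 - pe < .Machine$double.eps^0.5)
    stop("degenerate marginals (pe = 1): kappa undefined")
  kap <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt (1969) asymptotic variance for kappa != 0
  A <- sum(diag(p) * (1 - (pi_ + pj_) * (1 - kap))^2)
  B <- (1 - kap)^2 * (p[1, 2] * (pj_[1] + pi_[2])^2 +
                      p[2, 1] * (pj_[2] + pi_[1])^2)
  C <- (kap - pe * (1 - kap))^2
  se <- sqrt(max(A + B - C, 0) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - conf) / 2)
  structure(list(kappa = kap, se = se,
                 ci95 = c(kap - z * se, kap + z * se),
                 po = po, pe = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.2f (95%% CI %.2f-%.2f), n = %d\n",
              x$kappa, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Percent agreement of a paired table
#'
#' @param tab A [table2x2()].
#' @return List with `concordant_positive`, `concordant_negative` and
#'   `overall` fractions.
#' @export
percent_agreement <- function(tab) {
  stopifnot(inherits(tab, "table2x2"))
  list(concordant_positive = tab$a / tab$n,
       concordant_negative = tab$d / tab$n,
       overall = (tab$a + tab$d) / tab$n)
}

# exact or Wilson CI for a binomial proportion
binom_ci <- function(x, n, conf = 0.95, method = c("clopper-pearson",
                                                   "wilson")) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "clopper-pearson") {
    as.numeric(binom.test(x, n, conf.level = conf)$conf.int)
  } else {
    z <- qnorm(1 - (1 - conf) / 2)
    ph <- x / n
    den <- 1 + z^2 / n
    ctr <- (ph + z^2 / (2 * n)) / den
    hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    c(max(0, ctr - hw), min(1, ctr + hw))
  }
}

#' Diagnostic / prognostic classification metrics with exact CIs
#'
#' Sensitivity, specificity, PPV and NPV for a 2x2 table oriented as
#' exposure (rows) vs outcome (columns), each with a 95% confidence interval
#' (Clopper-Pearson exact by default, Wilson as option). Metrics with a zero
#' denominator are returned as `NA` with an explanatory message attribute.
#'
#' @param tab A [table2x2()] (`a` = exposed with outcome, `b` = exposed
#'   without, `c` = unexposed with outcome, `d` = unexposed without).
#' @param conf Confidence level.
#' @param method CI method.
#' @return A data.frame with columns `metric`, `estimate`, `lower`, `upper`,
#'   `x`, `n`.
#' @export
diagnostic_metrics <- function(tab, conf = 0.95,
                               method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(tab, "table2x2"))
  method <- match.arg(method)
  defs <- list(sensitivity = c(tab$a, tab$a + tab$c),
               specificity = c(tab$d, tab$b + tab$d),
               ppv = c(tab$a, tab$a + tab$b),
               npv = c(tab$d, tab$c + tab$d))
  rows <- lapply(names(defs), function(nm) {
    x <- defs[[nm]][1]; n <- defs[[nm]][2]
    if (n == 0) {
      message(sprintf("%s undefined: zero denominator", nm))
      return(data.frame(metric = nm, estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, x = x, n = n))
    }
    ci <- binom_ci(x, n, conf, method)
    data.frame(metric = nm, estimate = x / n, lower = ci[1], upper = ci[2],
               x = x, n = n)
  })
  do.call(rbind, rows)
}
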