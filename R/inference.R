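#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`; `k` counts every
#' estimated parameter including the residual variance, so a
#' Gaussian intercept-only model has `k = 2`.
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters (including sigma^2).
#' @param n sample size; must exceed `k + 1`.
#' @return the criterion value.
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc requires n > k + 1", call. = FALSE)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Marginality-respecting candidate model enumeration
#'
#' All subsets of the supplied terms such that every interaction
#' (`"a:b"`) is accompanied by both of its main effects; the null
#' (intercept-only) model is included.  This is the candidate set a
#' dredge-style all-subsets selection explores.
#'
#' @param terms character vector of main effects and `:` interactions.
#' @return list of character vectors (the null model is `character(0)`).
#' @export
enumerate_models <- function(terms) {
  n <- length(terms)
  parents <- lapply(terms, function(tm) strsplit(tm, ":", fixed = TRUE)[[1]])
  out <- list()
  for (mask in 0:(2^n - 1)) {
    inc <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    set <- terms[inc]
    ok <- all(vapply(which(inc), function(i) {
      p <- parents[[i]]
      length(p) == 1 || all(p %in% set)
    }, logical(1)))
    if (ok) out[[length(out) + 1]] <- set
  }
  out
}

model_label <- function(terms) {
  if (length(terms) == 0) "Null" else paste(terms, collapse = " + ")
}

fit_one_model <- function(terms, response, data) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fml <- as.formula(paste(response, "~", rhs))
  fit <- lm(fml, data = data)
  ll <- logLik(fit)
  n <- length(residuals(fit))
  rss <- sum(residuals(fit)^2)
  # a saturated model triggers summary.lm's perfect-fit warning; it is
  # flagged as degenerate below, so extract R2 quietly
  r2 <- suppressWarnings(summary(fit)$r.squared)
  degenerate <- rss < 1e-12 * max(var(data[[response]]), 1e-300) * (n - 1)
  list(terms = terms, label = model_label(terms), fit = fit,
       logLik = as.numeric(ll), k = attr(ll, "df"), n = n,
       rss = rss, r2 = r2, degenerate = degenerate)
}

#' All-subsets model selection ranked by AICc
#'
#' Fits every marginality-respecting candidate model of `response` on the
#' supplied terms (Gaussian identity-link GLMs via OLS), ranks by AICc and
#' attaches Akaike weights computed over the full candidate set.
#'
#' @param data data frame.
#' @param response response column name.
#' @param terms candidate terms (main effects and `:` interactions).
#' @return object of class `model_table`: a data frame with columns
#'   `model`, `df`, `logLik`, `AICc`, `dAICc`, `weight`, `R2`, sorted by
#'   AICc, with the fitted models in attribute `fits`.
#' @export
model_selection <- function(data, response, terms) {
  specs <- enumerate_models(terms)
  fits <- lapply(specs, fit_one_model, response = response, data = data)
  deg <- vapply(fits, `[[`, logical(1), "degenerate")
  if (any(deg)) {
    warning("dropping ", sum(deg), " saturated model(s) with ~zero RSS")
    fits <- fits[!deg]
  }
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  k <- vapply(fits, `[[`, numeric(1), "k")
  n <- vapply(fits, `[[`, numeric(1), "n")
  ic <- aicc(ll, k, n)
  d <- ic - min(ic)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "label"),
    df = k, logLik = ll, AICc = ic, dAICc = d, weight = w,
    R2 = vapply(fits, `[[`, numeric(1), "r2"),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$AICc)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  attr(tab, "response") <- response
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' Reporting filter: models within a dAICc cut of the best
#'
#' @param table a `model_table`.
#' @param delta_max the cut (2 by convention).
#' @return the filtered table (weights are not renormalized).
#' @export
top_models <- function(table, delta_max = 2) {
  out <- table[table$dAICc < delta_max, , drop = FALSE]
  attr(out, "fits") <- attr(table, "fits")[table$dAICc < delta_max]
  out
}

#' Relative importance weight of a term
#'
#' Sum of the Akaike weights of all candidate models containing the term
#' (interaction order is normalized, so `"sex:tarsi_index"` and
#' `"tarsi_index:sex"` are the same term).
#'
#' @param term term name.
#' @param table a `model_table` over the full candidate set.
#' @return a weight in \[0, 1\].
#' @export
riw <- function(term, table) {
  fits <- attr(table, "fits")
  key <- normalize_term(term)
  has <- vapply(fits, function(f) {
    key %in% vapply(f$terms, normalize_term, character(1))
  }, logical(1))
  sum(table$weight[has])
}

normalize_term <- function(tm) {
  paste(sort(strsplit(tm, ":", fixed = TRUE)[[1]]), collapse = ":")
}

coef_key <- function(nm) {
  paste(sort(strsplit(nm, ":", fixed = TRUE)[[1]]), collapse = ":")
}

#' Conditional (natural) model averaging
#'
#' Averages coefficients over the models of the top set (dAICc below
#' `delta_max`), each coefficient over only the models that contain it,
#' with weights renormalized over that subset.  The unconditional
#' standard error follows Burnham & Anderson:
#' `SE = sqrt(sum_w w * (SE_m^2 + (b_m - b_bar)^2))`; the 95% CI is
#' `b_bar +/- 1.96 SE`.  When the top model alone carries weight of 0.9
#' or more, its coefficients are returned unaveraged (flagged by the
#' attribute `single_model`).
#'
#' @param table a `model_table`.
#' @param delta_max the top-set cut.
#' @param conf normal quantile multiplier basis (0.95 -> 1.96).
#' @return data frame `term`, `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   `significant` (CI excludes zero), `riw` (over the full set).
#' @export
model_average <- function(table, delta_max = 2, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  fits <- attr(table, "fits")
  if (table$weight[1] >= 0.9 || nrow(table) == 1 || table$dAICc[2] >= delta_max) {
    f <- fits[[1]]
    sm <- summary(f$fit)$coefficients
    out <- data.frame(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      stringsAsFactors = FALSE
    )
    single <- TRUE
  } else {
    keep <- table$dAICc < delta_max
    w <- table$weight[keep] / sum(table$weight[keep])
    fs <- fits[keep]
    per <- lapply(seq_along(fs), function(i) {
      sm <- summary(fs[[i]]$fit)$coefficients
      data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                 w = w[i], stringsAsFactors = FALSE)
    })
    allc <- do.call(rbind, per)
    out <- do.call(rbind, lapply(split(allc, allc$term), function(d) {
      wr <- d$w / sum(d$w)
      b <- sum(wr * d$estimate)
      se <- sqrt(sum(wr * (d$se^2 + (d$estimate - b)^2)))
      data.frame(term = d$term[1], estimate = b, se = se,
                 stringsAsFactors = FALSE)
    }))
    single <- FALSE
  }
  out$ci_lo <- out$estimate - z * out$se
  out$ci_hi <- out$estimate + z * out$se
  out$significant <- out$ci_lo > 0 | out$ci_hi < 0
  terms_in_table <- unique(unlist(lapply(fits, `[[`, "terms")))
  out$riw <- vapply(out$term, function(nm) {
    mt <- match_coef_term(nm, terms_in_table)
    if (is.na(mt)) NA_real_ else riw(mt, table)
  }, numeric(1))
  rownames(out) <- NULL
  attr(out, "single_model") <- single
  out
}

# map a coefficient name (possibly with a factor level suffix, e.g.
# "sexM" or "sexM:tarsi_index") back to its model term.
match_coef_term <- function(coef_name, terms) {
  if (coef_name == "(Intercept)") return(NA_character_)
  parts <- strsplit(coef_name, ":", fixed = TRUE)[[1]]
  for (tm in terms) {
    tparts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(tparts) != length(parts)) next
    hit <- all(vapply(seq_along(parts), function(i) {
      any(startsWith(parts[i], tparts) | parts[i] == tparts)
    }, logical(1))) &&
      all(vapply(tparts, function(tp) any(startsWith(parts, tp)),
                 logical(1)))
    if (hit) return(tm)
  }
  NA_character_
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor
#' `j` on the remaining predictors (main effects only; factors must be
#' numerically coded).  Perfect collinearity yields `Inf`.
#'
#' @param data data frame of numeric predictors.
#' @param predictors column names; default all columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(data, predictors = names(data)) {
  if (length(predictors) < 2) {
    stop("VIF needs at least two predictors", call. = FALSE)
  }
  vapply(predictors, function(p) {
    others <- setdiff(predictors, p)
    fml <- as.formula(paste(p, "~", paste(others, collapse = " + ")))
    r2 <- suppressWarnings(summary(lm(fml, data = data))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Pooled-variance and paired t tests
#'
#' Thin wrappers around [stats::t.test()] matching the conventions of a
#' 16-vs-16 morphometric comparison (pooled variance, df = n1 + n2 - 2)
#' and a within-individual comparison (paired, df = n - 1), with a guard
#' for zero-variance input.
#'
#' @param a,b numeric samples (equal length when `paired`).
#' @param paired paired test?
#' @return list with `t`, `df`, `p`.
#' @export
t_test2 <- function(a, b, paired = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least two observations per group", call. = FALSE)
  }
  if (paired && length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  novar <- if (paired) sd(a - b) == 0 else sd(a) == 0 && sd(b) == 0
  if (novar) {
    df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, df = df, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = !paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
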