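#' Stack per-shift fused tables into a modeling data frame
#'
#' Binds one fused (or plain) window table per officer into level-1 data for
#' [fit_mmta()], adding the officer identifier and a `time` column in hours
#' coded zero at each shift start (baseline drift such as sweat accumulation
#' at the electrodes makes per-shift time the natural clock).
#'
#' @param tables list of `window_table` / `fused_table` data frames.
#' @param officer_ids character vector, one id per table.
#' @return data frame with `officer_id`, `time` and every table column.
#' @export
stack_shifts <- function(tables, officer_ids) {
  stopifnot(length(tables) == length(officer_ids))
  out <- do.call(rbind, lapply(seq_along(tables), function(i) {
    d <- as.data.frame(tables[[i]])
    d$officer_id <- as.character(officer_ids[i])
    d$time <- d$elapsed_time / 3600
    d
  }))
  rownames(out) <- NULL
  out
}

df_label <- c(satterthwaite = "Satterthwaite",
              `kenward-roger` = "Kenward-Roger",
              residual = "residual")

#' Fit a mixed-model trajectory analysis
#'
#' Fits the two-level linear mixed model
#' `Y_it = b0 + u0i + b1 time + u1i time + b2 Intx_it + b3 (Intx x time)_it + e_it`
#' (or any other fixed-effect structure given by `formula`): each officer's
#' window series at level 1, officers at level 2, with random intercepts and
#' slopes `(u0i, u1i)` and a choice of residual error structure. REML is the
#' default for reporting because full maximum likelihood underestimates
#' variance components in small samples; refit with `method = "ML"` for
#' likelihood-based model comparison ([compare_models()]). Fixed-effect
#' inference uses a small-sample degrees-of-freedom correction —
#' Satterthwaite by default, Kenward-Roger on request where the numerical
#' machinery supports it (independent errors; its cost grows quadratically
#' with the number of observations, so reserve it for modest samples) — and
#' the method actually used is recorded in the fit. Rows with missing values
#' in any model variable are dropped listwise with a message.
#'
#' @param formula fixed-effects formula, e.g.
#'   `avg_eda_level ~ time * intervention`.
#' @param data modeling data frame (see [stack_shifts()]).
#' @param officer name of the grouping column; at least 2 officers are
#'   required whenever random effects are requested.
#' @param random one-sided formula for the per-officer random effects
#'   (default `~ 1 + time`: random intercept and slope), or `NULL` for a
#'   fixed-effects-only ordinary least squares fit.
#' @param error residual error structure: `"independent"`, `"ar1"`
#'   (first-order autoregressive within officer) or `"toeplitz"` (banded
#'   correlation out to `bands` lags, realized as a moving-average process
#'   of that order).
#' @param bands number of correlated lags for `error = "toeplitz"`.
#' @param method `"REML"` (reporting) or `"ML"` (model comparison).
#' @param df degrees-of-freedom method for fixed-effect tests. Correlated
#'   error structures are fit with a different engine that provides
#'   between-within (residual) degrees of freedom only; the fit records
#'   what was used.
#' @return an object of class `mmta_fit`; see [summary.mmta_fit()].
#' @export
fit_mmta <- function(formula, data, officer = "officer_id",
                     random = ~ 1 + time,
                     error = c("independent", "ar1", "toeplitz"),
                     bands = 2L,
                     method = c("REML", "ML"),
                     df = c("satterthwaite", "kenward-roger", "residual")) {
  error <- match.arg(error)
  method <- match.arg(method)
  df <- match.arg(df)
  cl <- match.call()
  data <- as.data.frame(data)

  vars <- unique(c(all.vars(formula),
                   if (!is.null(random)) all.vars(random),
                   if (!is.null(random) || error != "independent") officer))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("model variables not in data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  keep <- complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped)
    message("fit_mmta: dropping ", n_dropped,
            " row(s) with missing model variables")
  d <- data[keep, , drop = FALSE]

  fixed_terms <- attr(terms(formula), "term.labels")
  out <- list(call = cl, formula = formula, officer = officer,
              random = random, error = error, method = method,
              fixed_terms = fixed_terms, n_dropped = n_dropped)

  if (is.null(random) && error == "independent") {
    fit <- stats::lm(formula, data = d)
    sm <- summary(fit)
    ct <- cbind(sm$coefficients[, 1:2, drop = FALSE],
                df = fit$df.residual,
                sm$coefficients[, 3:4, drop = FALSE])
    colnames(ct) <- c("estimate", "se", "df", "t", "p")
    out <- c(out, list(
      engine = "lm", fit = fit, coefficients = ct, G = NULL,
      sigma = sm$sigma, corr = NULL,
      logLik = as.numeric(logLik(fit)), npar = length(coef(fit)) + 1L,
      AIC = AIC(fit), BIC = BIC(fit),
      df_method = "residual", n_obs = nrow(d), n_officers = NA_integer_,
      converged = TRUE, messages = character(0)))
    class(out) <- "mmta_fit"
    return(out)
  }

  n_off <- length(unique(d[[officer]]))
  if (!is.null(random) && n_off < 2)
    stop("random effects require at least 2 officers", call. = FALSE)

  if (error == "independent") {
    rand_rhs <- paste(deparse(random[[2]]), collapse = " ")
    lf <- as.formula(paste(deparse(formula[[2]]), "~",
                           paste(deparse(formula[[3]]), collapse = " "),
                           "+ (", rand_rhs, "|", officer, ")"))
    fit <- lmerTest::lmer(lf, data = d, REML = (method == "REML"))
    if (df == "kenward-roger" && !requireNamespace("pbkrtest", quietly = TRUE))
      stop("Kenward-Roger degrees of freedom need the pbkrtest package",
           call. = FALSE)
    if (df == "residual") {
      ct0 <- summary(fit, ddf = "lme4")$coefficients
      ct <- cbind(ct0[, 1:2, drop = FALSE],
                  df = nrow(d) - length(lme4::fixef(fit)),
                  t = ct0[, 3])
      ct <- cbind(ct, p = 2 * pt(-abs(ct[, "t"]), ct[, "df"]))
    } else {
      ct <- summary(fit, ddf = df_label[[df]])$coefficients
    }
    colnames(ct) <- c("estimate", "se", "df", "t", "p")
    vc <- lme4::VarCorr(fit)
    G <- as.matrix(vc[[officer]])
    attr(G, "stddev") <- attr(vc[[officer]], "stddev")
    ll <- logLik(fit)
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    out <- c(out, list(
      engine = "lmer", fit = fit, coefficients = ct,
      G = G, sigma = stats::sigma(fit), corr = NULL,
      logLik = as.numeric(ll), npar = attr(ll, "df"),
      AIC = AIC(fit), BIC = BIC(fit),
      df_method = df, n_obs = nrow(d), n_officers = n_off,
      converged = length(msgs) == 0 || lme4::isSingular(fit),
      messages = if (is.null(msgs)) character(0) else msgs))
  } else {
    if (df != "residual")
      message("fit_mmta: correlated error structures use residual ",
              "(between-within) degrees of freedom")
    d$.obs <- stats::ave(seq_len(nrow(d)), d[[officer]], FUN = seq_along)
    cor_struct <- if (error == "ar1")
      nlme::corAR1(form = as.formula(paste("~ .obs |", officer)))
    else
      nlme::corARMA(form = as.formula(paste("~ .obs |", officer)),
                    p = 0, q = as.integer(bands))
    rnd <- if (is.null(random)) NULL else
      as.formula(paste("~", paste(deparse(random[[2]]), collapse = " "),
                       "|", officer))
    fit <- if (is.null(rnd))
      nlme::gls(formula, data = d, correlation = cor_struct, method = method)
    else
      nlme::lme(fixed = formula, random = rnd, data = d,
                correlation = cor_struct, method = method,
                control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                           msMaxIter = 200))
    sm <- summary(fit)
    tt <- sm$tTable
    ct <- if (ncol(tt) == 5)
      tt[, c("Value", "Std.Error", "DF", "t-value", "p-value"), drop = FALSE]
    else  # gls: no DF column
      cbind(tt[, 1:2, drop = FALSE],
            df = nrow(d) - nrow(tt), tt[, 3:4, drop = FALSE])
    colnames(ct) <- c("estimate", "se", "df", "t", "p")
    G <- if (is.null(rnd)) NULL else {
      g <- try(nlme::getVarCov(fit), silent = TRUE)
      if (inherits(g, "try-error")) NULL else unclass(g)
    }
    phi <- coef(fit$modelStruct$corStruct, unconstrained = FALSE)
    ll <- logLik(fit)
    out <- c(out, list(
      engine = if (is.null(rnd)) "gls" else "lme", fit = fit,
      coefficients = ct, G = G, sigma = fit$sigma, corr = phi,
      logLik = as.numeric(ll), npar = attr(ll, "df"),
      AIC = AIC(fit), BIC = BIC(fit),
      df_method = "residual", n_obs = nrow(d), n_officers = n_off,
      converged = TRUE, messages = character(0)))
  }
  class(out) <- "mmta_fit"
  out
}

#' @export
print.mmta_fit <- function(x, ...) {
  cat(sprintf("<mmta_fit> %s, %s errors, %s estimation (%s df)\n",
              deparse(x$formula), x$error, x$method, df_label[[x$df_method]]))
  cat(sprintf("  %d observations, %s officer(s); logLik %.2f, AIC %.2f\n",
              x$n_obs,
              if (is.na(x$n_officers)) "-" else x$n_officers,
              x$logLik, x$AIC))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Summarize a mixed-model trajectory fit
#'
#' @param object an `mmta_fit`.
#' @param ... unused.
#' @return `object`, invisibly; prints fixed effects with corrected-df
#'   tests, random-effect covariance, residual parameters and fit statistics.
#' @export
summary.mmta_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$G)) {
    cat("Random-effect covariance (G):\n")
    print(round(unclass(object$G)[seq_len(nrow(object$G)),
                                  seq_len(ncol(object$G)), drop = FALSE], 6))
  }
  cat(sprintf("Residual SD %.4f", object$sigma))
  if (!is.null(object$corr) && length(object$corr))
    cat("; correlation parameter(s): ",
        paste(sprintf("%.3f", object$corr), collapse = ", "))
  cat(sprintf("\nAIC %.2f, BIC %.2f (%s)", object$AIC, object$BIC,
              object$method))
  if (!object$converged || length(object$messages))
    cat("\nConvergence notes: ", paste(object$messages, collapse = "; "))
  cat("\n")
  invisible(object)
}

#' @export
coef.mmta_fit <- function(object, ...)
  setNames(object$coefficients[, "estimate"],
           rownames(object$coefficients))

#' @export
vcov.mmta_fit <- function(object, ...) as.matrix(vcov(object$fit))

#' @export
logLik.mmta_fit <- function(object, ...)
  structure(object$logLik, df = object$npar, class = "logLik")

#' @export
predict.mmta_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$fit, ...)
  else predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.mmta_fit <- function(object, ...) residuals(object$fit, ...)

#' @export
fitted.mmta_fit <- function(object, ...) fitted(object$fit, ...)

#' Wald confidence intervals with corrected degrees of freedom
#'
#' @param object an `mmta_fit`.
#' @param parm coefficients to include (names or indices; default all).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix of lower/upper bounds.
#' @export
confint.mmta_fit <- function(object, parm = NULL, level = 0.95, ...) {
  ct <- object$coefficients
  if (!is.null(parm)) ct <- ct[parm, , drop = FALSE]
  a <- (1 - level) / 2
  q <- qt(1 - a, ct[, "df"])
  out <- cbind(ct[, "estimate"] - q * ct[, "se"],
               ct[, "estimate"] + q * ct[, "se"])
  colnames(out) <- paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")
  rownames(out) <- rownames(ct)
  out
}

#' Best linear unbiased predictors of the per-officer random effects
#'
#' @param fit an `mmta_fit` with random effects.
#' @return data frame of per-officer random-effect predictions (u0i and,
#'   when a random slope was fit, u1i).
#' @export
blup <- function(fit) {
  stopifnot(inherits(fit, "mmta_fit"))
  if (fit$engine == "lmer") as.data.frame(lme4::ranef(fit$fit)[[fit$officer]])
  else if (fit$engine == "lme") as.data.frame(nlme::ranef(fit$fit))
  else stop("fit has no random effects", call. = FALSE)
}

#' Rank candidate models by information criteria
#'
#' All fits must use full maximum likelihood on the same data; REML
#' likelihoods are not comparable across fixed-effect structures and mixing
#' them is an error. Models are ranked by AIC (ties share a rank), BIC is
#' reported alongside, and every nested pair — one model's fixed terms a
#' subset of the other's with fewer parameters overall — also gets a
#' likelihood-ratio statistic.
#'
#' @param ... `mmta_fit` objects, optionally named.
#' @return an object of class `mmta_comparison`: list with `table` (one row
#'   per model) and `lrt` (one row per nested pair).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "mmta_fit")) fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, TRUE, "mmta_fit")))
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("model", seq_along(fits))
  if (any(vapply(fits, `[[`, "", "method") != "ML"))
    stop("model comparison requires ML fits; refit with method = \"ML\"",
         call. = FALSE)
  if (length(unique(vapply(fits, `[[`, 0, "n_obs"))) > 1)
    stop("models were fit to different numbers of observations",
         call. = FALSE)
  tab <- data.frame(
    model = names(fits),
    npar = vapply(fits, `[[`, 0, "npar"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    BIC = vapply(fits, `[[`, 0, "BIC"),
    stringsAsFactors = FALSE
  )
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$rank <- rank(tab$AIC, ties.method = "min")
  lrt <- NULL
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    if (i == j) next
    nested <- all(fits[[i]]$fixed_terms %in% fits[[j]]$fixed_terms) &&
      tab$npar[i] < tab$npar[j]
    if (!nested) next
    stat <- 2 * (tab$logLik[j] - tab$logLik[i])
    ddf <- tab$npar[j] - tab$npar[i]
    lrt <- rbind(lrt, data.frame(
      reduced = tab$model[i], full = tab$model[j],
      chisq = stat, df = ddf,
      p = pchisq(max(stat, 0), ddf, lower.tail = FALSE),
      stringsAsFactors = FALSE))
  }
  structure(list(table = tab[order(tab$rank), ], lrt = lrt),
            class = "mmta_comparison")
}

#' @export
print.mmta_comparison <- function(x, ...) {
  cat("Model comparison (ML):\n")
  print(transform(x$table, logLik = round(logLik, 2), AIC = round(AIC, 2),
                  BIC = round(BIC, 2), dAIC = round(dAIC, 2)),
        row.names = FALSE)
  if (!is.null(x$lrt)) {
    cat("Likelihood-ratio tests (nested pairs):\n")
    print(transform(x$lrt, chisq = round(chisq, 3),
                    p = signif(p, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Contrast an outcome between call-phase classes
#'
#' Given per-window class labels (for instance high- versus low-stress call
#' types), reports descriptive mean and SD per class and a model-based
#' contrast with the class as a fixed effect: a random-intercept mixed model
#' when the data span two or more officers, an ordinary linear model
#' otherwise. Windows with a missing label or outcome are excluded.
#'
#' @param data modeling data frame.
#' @param outcome name of the outcome column.
#' @param label name of the class-label column, or a vector of labels with
#'   one entry per row of `data`.
#' @param officer name of the grouping column (ignored if absent).
#' @param ref reference class; defaults to the first factor level.
#' @param covariates names of columns to include as statistical control
#'   fixed effects — typically `"time"`, since call phases are confounded
#'   with time-of-shift whenever the tonic level drifts over a shift.
#' @return an object of class `phase_contrast`: list with `descriptives`
#'   (class, n, mean, sd), `contrast` (estimate, se, df, t, p per non-
#'   reference class) and the underlying `fit`.
#' @export
phase_contrast <- function(data, outcome, label, officer = "officer_id",
                           ref = NULL, covariates = NULL) {
  data <- as.data.frame(data)
  lab <- if (length(label) == 1L && is.character(label) &&
             label %in% names(data)) data[[label]] else label
  stopifnot(length(lab) == nrow(data))
  keep <- !is.na(lab) & !is.na(data[[outcome]])
  if (length(covariates))
    keep <- keep & complete.cases(data[, covariates, drop = FALSE])
  d <- data.frame(.y = data[[outcome]][keep],
                  .class = factor(as.character(lab[keep])))
  for (cv in covariates) d[[cv]] <- data[[cv]][keep]
  if (!is.null(ref)) d$.class <- stats::relevel(d$.class, ref = ref)
  if (nlevels(d$.class) < 2)
    stop("single-class input: need at least 2 classes", call. = FALSE)
  counts <- table(d$.class)
  if (any(counts < 2))
    stop("every class needs at least 2 windows", call. = FALSE)

  desc <- data.frame(
    class = levels(d$.class),
    n = as.integer(counts),
    mean = as.numeric(tapply(d$.y, d$.class, mean)),
    sd = as.numeric(tapply(d$.y, d$.class, sd)),
    stringsAsFactors = FALSE
  )

  rhs <- paste(c(".class", covariates), collapse = " + ")
  multi <- officer %in% names(data) &&
    length(unique(data[[officer]][keep])) >= 2 &&
    var(d$.y) > 0  # a constant outcome has nothing for a mixed model
  if (multi) {
    d$.off <- factor(as.character(data[[officer]][keep]))
    fit <- lmerTest::lmer(as.formula(paste(".y ~", rhs, "+ (1 | .off)")),
                          data = d)
    ct <- summary(fit, ddf = "Satterthwaite")$coefficients
    engine <- "lmer"
  } else {
    fit <- stats::lm(as.formula(paste(".y ~", rhs)), data = d)
    sm <- summary(fit)
    ct <- cbind(sm$coefficients[, 1:2, drop = FALSE],
                df = fit$df.residual,
                sm$coefficients[, 3:4, drop = FALSE])
    engine <- "lm"
  }
  colnames(ct) <- c("estimate", "se", "df", "t", "p")
  contrast <- ct[grepl("^\\.class", rownames(ct)), , drop = FALSE]
  rownames(contrast) <- sub("^\\.class", "", rownames(contrast))
  # degenerate data (zero residual variance): a zero contrast is certain,
  # not undefined; tolerance absorbs floating-point noise of a perfect fit
  eps <- 1e-10 * max(1, mean(abs(d$.y)))
  deg <- contrast[, "se"] < eps & abs(contrast[, "estimate"]) < eps
  if (any(deg)) {
    contrast[deg, "estimate"] <- 0
    contrast[deg, "se"] <- 0
    contrast[deg, "t"] <- 0
    contrast[deg, "p"] <- 1
  }
  structure(list(descriptives = desc, contrast = contrast,
                 engine = engine, fit = fit),
            class = "phase_contrast")
}

#' @export
print.phase_contrast <- function(x, ...) {
  cat("Per-class outcome:\n")
  print(transform(x$descriptives, mean = round(mean, 4), sd = round(sd, 4)),
        row.names = FALSE)
  cat(sprintf("Model-based contrast (%s):\n", x$engine))
  print(round(x$contrast, 6))
  invisible(x)
}

#' Simulate level-1/level-2 trajectory data with known parameters
#'
#' Generates the two-level model [fit_mmta()] estimates:
#' `y = b0 + u0i + (b1 + u1i) time + b2 intx + b3 intx*time + e`, with
#' normally distributed officer effects and, optionally, first-order
#' autoregressive residuals of marginal SD `sigma`. `time` is hours from
#' shift start (20-second windows); the intervention indicator alternates in
#' six equal blocks per shift (two-hour blocks at the default length) so it
#' varies within officer without tracking time.
#'
#' @param n_officers number of officers (level-2 units).
#' @param n_windows 20-second windows per officer.
#' @param beta fixed effects `c(b0, b1, b2, b3)` for intercept, time,
#'   intervention, intervention-by-time.
#' @param sd_u0,sd_u1 SDs of the random intercept and slope.
#' @param sigma marginal residual SD.
#' @param rho residual AR(1) parameter (0 = independent).
#' @param seed integer seed.
#' @return data frame with `officer_id`, `window`, `time`, `intx`, `y`.
#' @export
simulate_mmta <- function(n_officers = 3, n_windows = 2160,
                          beta = c(0.3, 0, 0.6, 0),
                          sd_u0 = 0.1, sd_u1 = 0, sigma = 0.3, rho = 0,
                          seed = 1L) {
  set.seed(seed)
  w <- seq_len(n_windows)
  time <- (w - 1) * 20 / 3600
  block <- ceiling(n_windows / 6)
  intx <- as.numeric(((w - 1) %/% block) %% 2 == 1)
  out <- vector("list", n_officers)
  for (i in seq_len(n_officers)) {
    u0 <- rnorm(1, 0, sd_u0)
    u1 <- rnorm(1, 0, sd_u1)
    if (rho == 0) {
      e <- rnorm(n_windows, 0, sigma)
    } else {
      # stationary AR(1): seed from the marginal distribution
      innov <- rnorm(n_windows, 0, sigma * sqrt(1 - rho^2))
      e <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                    init = rnorm(1, 0, sigma)))
    }
    out[[i]] <- data.frame(
      officer_id = sprintf("officer-%d", i), window = w, time = time,
      intx = intx,
      y = beta[1] + u0 + (beta[2] + u1) * time + beta[3] * intx +
        beta[4] * intx * time + e
    )
  }
  do.call(rbind, out)
}
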