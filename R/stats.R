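# Inferential stage: factorial mixed-effects models with subject random
# intercepts, estimated marginal means (EMMs) and Wald contrasts,
# Holm-Bonferroni correction, and questionnaire predictor screening.

#' Fit the factorial mixed-effects model
#'
#' Fits `response ~ threat * tti * behavior + (1 | subject)`: full-factorial
#' fixed effects with all interactions and a random intercept per subject.
#' Continuous responses use a Gaussian linear mixed model; binary responses
#' a logistic mixed model with the Laplace approximation. On convergence
#' failure the fit is retried with each available alternative optimizer, and
#' binary models finally fall back to dropping the integration over random
#' effects (`nAGQ = 0`).
#'
#' Rows with a missing response are dropped listwise.
#'
#' @param data Data frame with columns `subject`, `threat`, `tti`,
#'   `behavior` and the response.
#' @param response Name of the response column.
#' @param family `"gaussian"` or `"binomial"` (binary responses coded 0/1 or
#'   logical).
#' @param factors Names of the factorial predictors.
#' @param subject Name of the subject-identifier column.
#' @return The fitted `merMod`, with attribute `optimizer_used`.
#' @export
fit_factorial_mixed <- function(data, response,
                                family = c("gaussian", "binomial"),
                                factors = c("threat", "tti", "behavior"),
                                subject = "subject") {
  family <- match.arg(family)
  stopifnot(all(c(factors, subject, response) %in% names(data)))
  d <- data[!is.na(data[[response]]), , drop = FALSE]
  for (f in factors) d[[f]] <- factor(d[[f]])
  d[[subject]] <- factor(d[[subject]])
  if (nlevels(d[[subject]]) < 2L) stop("need at least 2 subjects")
  present <- unique(d[, factors, drop = FALSE])
  full <- expand.grid(lapply(d[, factors, drop = FALSE], levels),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(x) do.call(paste, c(lapply(x, as.character), sep = "\r"))
  empty <- full[!key(full) %in% key(present), , drop = FALSE]
  if (nrow(empty) > 0L) {
    stop("rank-deficient design; empty cells: ",
         paste(key(empty), collapse = "; "))
  }
  if (family == "binomial") {
    d[[response]] <- as.numeric(d[[response]])
    if (!all(d[[response]] %in% c(0, 1))) {
      stop("binary response must be 0/1")
    }
  }
  fml <- stats::as.formula(paste0(
    response, " ~ ", paste(factors, collapse = " * "),
    " + (1 | ", subject, ")"))

  optimizers <- list(
    list(optimizer = "nloptwrap"), list(optimizer = "bobyqa"),
    list(optimizer = "Nelder_Mead"),
    list(optimizer = "nloptwrap",
         optCtrl = list(algorithm = "NLOPT_LN_NELDERMEAD"))
  )
  try_fit <- function(ctrl_args, nAGQ = 1L) {
    warns <- character(0)
    fit <- withCallingHandlers(
      tryCatch({
        if (family == "gaussian") {
          lme4::lmer(fml, data = d,
                     control = do.call(lme4::lmerControl, ctrl_args))
        } else {
          lme4::glmer(fml, data = d, family = stats::binomial(),
                      nAGQ = nAGQ,
                      control = do.call(lme4::glmerControl, ctrl_args))
        }
      }, error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(fit = fit, converged = !inherits(fit, "error") &&
           !any(grepl("converge|Hessian", warns, ignore.case = TRUE)))
  }

  last <- NULL
  for (i in seq_along(optimizers)) {
    res <- try_fit(optimizers[[i]])
    if (!inherits(res$fit, "error")) last <- res
    if (res$converged) {
      attr(res$fit, "optimizer_used") <- optimizers[[i]]$optimizer
      return(res$fit)
    }
  }
  if (family == "binomial") {
    res <- try_fit(optimizers[[1]], nAGQ = 0L)
    if (!inherits(res$fit, "error")) {
      attr(res$fit, "optimizer_used") <- "nloptwrap (nAGQ = 0)"
      return(res$fit)
    }
  }
  if (is.null(last)) stop("model fitting failed for response ", response)
  attr(last$fit, "optimizer_used") <- "best non-converged fit"
  warning("model for ", response, " did not fully converge; ",
          "returning last fit")
  last$fit
}

#' Estimated marginal means for each design cell
#'
#' Model predictions for every cell of the factorial design with random
#' effects at zero. For binomial models the link-scale mean is accompanied
#' by the response-scale probability (delta-method SE).
#'
#' @param model A `merMod` from [fit_factorial_mixed()].
#' @return Data frame (class `emm_grid`) with one row per cell: the factor
#'   levels, `emmean` and `SE` on the link scale, and for binomial fits
#'   `prob` and `prob_SE`. The full EMM covariance matrix is attached as
#'   attribute `"V"`.
#' @export
estimated_marginal_means <- function(model) {
  fixed <- lme4::nobars(stats::formula(model))
  trms <- stats::delete.response(stats::terms(fixed))
  mf <- stats::model.frame(model)
  vars <- all.vars(trms)
  grid <- expand.grid(lapply(mf[vars], levels), KEEP.OUT.ATTRS = FALSE)
  X <- stats::model.matrix(trms, grid)
  beta <- lme4::fixef(model)
  V_beta <- as.matrix(stats::vcov(model))
  emm <- as.numeric(X %*% beta)
  V <- X %*% V_beta %*% t(X)
  out <- cbind(grid, emmean = emm, SE = sqrt(diag(V)))
  if (inherits(model, "glmerMod")) {
    p <- stats::plogis(emm)
    out$prob <- p
    out$prob_SE <- out$SE * p * (1 - p)
  }
  attr(out, "V") <- V
  attr(out, "family") <- if (inherits(model, "glmerMod")) "binomial"
                         else "gaussian"
  class(out) <- c("emm_grid", class(out))
  out
}

#' Wald contrast of estimated marginal means
#'
#' Linear combination of cell EMMs with delta-method standard error from the
#' model's coefficient covariance and a two-sided normal (Wald) test.
#'
#' @param emm An `emm_grid` from [estimated_marginal_means()].
#' @param weights Numeric weight vector, one entry per cell (rows of `emm`);
#'   difference contrasts must sum to zero.
#' @param label Optional contrast label.
#' @return One-row data frame: `contrast`, `estimate`, `SE`, `z`, `p`.
#' @export
emm_contrast <- function(emm, weights, label = "contrast") {
  if (length(weights) != nrow(emm)) {
    stop("weight length ", length(weights), " != number of cells ",
         nrow(emm))
  }
  V <- attr(emm, "V")
  est <- sum(weights * emm$emmean)
  se <- sqrt(as.numeric(t(weights) %*% V %*% weights))
  z <- if (se > 0) est / se else NA_real_
  data.frame(contrast = label, estimate = est, SE = se, z = z,
             p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Contrast between two cell groups
#'
#' Convenience wrapper: the contrast `mean(cells in A) - mean(cells in B)`,
#' with the groups given as filter expressions evaluated on the EMM grid
#' (e.g. `"behavior == 'attack' & tti == 'short'"`).
#'
#' @param emm An `emm_grid`.
#' @param filter_a,filter_b Filter expressions (strings) selecting the two
#'   cell groups.
#' @param label Contrast label.
#' @return One-row data frame as in [emm_contrast()].
#' @export
contrast_between_groups <- function(emm, filter_a, filter_b,
                                    label = "contrast") {
  sel <- function(f) {
    keep <- eval(parse(text = f)[[1]], envir = as.data.frame(emm))
    if (!any(keep)) stop("empty cell group for filter: ", f)
    keep
  }
  a <- sel(filter_a); b <- sel(filter_b)
  w <- as.numeric(a) / sum(a) - as.numeric(b) / sum(b)
  emm_contrast(emm, w, label)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces the running maximum, caps at 1, and returns the
#' adjusted values in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1L)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Default replication hypothesis set
#'
#' The eleven confirmatory behavioral hypotheses as group contrasts on the
#' factorial EMM grid: which summary statistic is the response, which cells
#' form each side of the contrast, and the response family. The exact
#' contrast weights of the original analysis are not published; these
#' definitions are editable best-guess defaults (each contrast compares
#' equal-weighted cell averages).
#'
#' @return Data frame with columns `hypothesis`, `response`, `family`,
#'   `filter_a`, `filter_b`, `description`.
#' @export
default_hypotheses <- function() {
  h <- function(hypothesis, response, family, filter_a, filter_b,
                description) {
    data.frame(hypothesis = hypothesis, response = response,
               family = family, filter_a = filter_a, filter_b = filter_b,
               description = description, stringsAsFactors = FALSE)
  }
  fast <- "c('elephant','bear','human','dog')"
  rbind(
    h("H1", "interrupted_escape", "binomial",
      "behavior == 'divert'", "behavior == 'attack'",
      "more interrupted escapes when the threat diverts"),
    h("H2", "escape_initiation_time", "gaussian",
      "behavior == 'attack' & tti == 'short'",
      "behavior == 'attack' & tti == 'long'",
      "earlier initiation under short time-to-impact when attacked"),
    h("H3", "initiated_escape", "binomial",
      "behavior == 'divert' & tti == 'short'",
      "behavior == 'divert' & tti == 'long'",
      "more initiations under short time-to-impact when threat diverts"),
    h("H4", "escaped_to_shelter", "binomial",
      paste0("behavior == 'attack' & tti == 'short' & threat %in% ",
             "c('elephant','bear')"),
      paste0("behavior == 'attack' & tti == 'short' & threat %in% ",
             "c('dog','human')"),
      "more shelter entries for fast feral than fast familiar threats"),
    h("H5", "escaped_to_shelter", "binomial",
      "behavior == 'attack' & threat == 'rock'",
      "behavior == 'attack' & threat != 'rock'",
      "fewer shelter entries for the ballistic rock"),
    h("H6", "escape_initiation_time", "gaussian",
      "tti == 'long' & threat == 'rock'",
      "tti == 'long' & threat != 'rock'",
      "latest initiation for the rock under long time-to-impact"),
    h("H7", "mean_speed", "gaussian",
      paste0("behavior == 'attack' & threat %in% ", fast),
      "behavior == 'attack' & threat %in% c('snake','spider')",
      "faster escape from fast threats when attacked"),
    h("H8", "body_orient_escape", "gaussian",
      "behavior == 'attack' & threat %in% c('snake','spider')",
      paste0("behavior == 'attack' & threat %in% ", fast),
      "body oriented more toward slow threats during escape"),
    h("H9", "head_orient_escape", "gaussian",
      "tti == 'long'", "tti == 'short'",
      "head oriented more toward the threat with more time"),
    h("H10", "mean_speed", "gaussian",
      "tti == 'short'", "tti == 'long'",
      "faster escape under short time-to-impact"),
    h("H11", "scan_appear", "gaussian",
      paste0("threat %in% c('elephant','bear','dog')"),
      "threat == 'human'",
      "less visual scanning after appearance of a human threat")
  )
}

#' Run the factorial contrast analysis over a hypothesis set
#'
#' For each hypothesis, fits (or reuses) the mixed model for its response,
#' computes cell EMMs, evaluates the group contrast, and finally applies
#' Holm-Bonferroni correction across the whole hypothesis family.
#'
#' @param summaries Epoch-summary data frame from [summarize_cohort()];
#'   binary responses `escaped_to_shelter` and `virtual_death` are derived
#'   from `outcome` if absent.
#' @param hypotheses Hypothesis table; see [default_hypotheses()].
#' @return Contrast table: one row per hypothesis with `estimate`, `SE`,
#'   `z`, `p`, `p_holm`.
#' @export
analyze_hypotheses <- function(summaries, hypotheses = default_hypotheses()) {
  d <- summaries
  if (!"escaped_to_shelter" %in% names(d)) {
    d$escaped_to_shelter <- as.numeric(d$outcome == "escape_to_shelter")
  }
  if (!"virtual_death" %in% names(d)) {
    d$virtual_death <- as.numeric(d$outcome == "virtual_death")
  }
  if (is.logical(d$initiated_escape)) {
    d$initiated_escape <- as.numeric(d$initiated_escape)
  }
  if ("interrupted_escape" %in% names(d) &&
      is.logical(d$interrupted_escape)) {
    d$interrupted_escape <- as.numeric(d$interrupted_escape)
  }
  models <- list()
  rows <- vector("list", nrow(hypotheses))
  for (i in seq_len(nrow(hypotheses))) {
    hy <- hypotheses[i, ]
    key <- paste(hy$response, hy$family)
    if (is.null(models[[key]])) {
      fit <- fit_factorial_mixed(d, hy$response, family = hy$family)
      models[[key]] <- estimated_marginal_means(fit)
    }
    rows[[i]] <- contrast_between_groups(models[[key]], hy$filter_a,
                                         hy$filter_b, label = hy$hypothesis)
  }
  out <- do.call(rbind, rows)
  out$p_holm <- holm_bonferroni(out$p)
  out
}

#' Screen questionnaire predictors of a behavioral outcome
#'
#' Retains questionnaire scores whose squared Pearson correlation with the
#' subject-level outcome exceeds 0.10, keeps at most the three highest-r2
#' among them, and always appends sex.
#'
#' @param scores Data frame of per-subject questionnaire scores (numeric
#'   columns) plus a `sex` column.
#' @param outcome Numeric vector, one value per subject (epoch statistics
#'   averaged within subject).
#' @param r2_threshold Squared-correlation screening threshold.
#' @param max_keep Maximum number of retained scores.
#' @return Character vector of selected predictor names (ending in
#'   `"sex"`), with attribute `r2` holding the screening values.
#' @export
questionnaire_select <- function(scores, outcome, r2_threshold = 0.10,
                                 max_keep = 3L) {
  num_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "sex")
  r2 <- vapply(num_cols, function(nm) {
    x <- scores[[nm]]
    if (stats::sd(x) == 0) {
      warning("constant score column excluded: ", nm)
      return(NA_real_)
    }
    stats::cor(x, outcome, use = "complete.obs")^2
  }, numeric(1))
  pass <- num_cols[!is.na(r2) & r2 > r2_threshold]
  pass <- pass[order(-r2[pass])]
  keep <- utils::head(pass, max_keep)
  out <- c(keep, "sex")
  attr(out, "r2") <- r2
  out
}

#' Between-person variance explained by selected predictors
#'
#' Coefficient of determination of the multiple regression of a
#' subject-level outcome on the selected predictors.
#'
#' @param scores Data frame of per-subject predictors (including `sex`).
#' @param outcome Numeric vector, one value per subject.
#' @param predictors Names of predictor columns (e.g. from
#'   [questionnaire_select()]).
#' @return R-squared in `[0, 1]`.
#' @export
between_person_variance_explained <- function(scores, outcome, predictors) {
  predictors <- unique(predictors)
  n <- length(outcome)
  if (n <= length(predictors) + 1L) {
    stop("need more subjects than predictors + 1")
  }
  d <- scores[, predictors, drop = FALSE]
  if ("sex" %in% predictors) d$sex <- factor(d$sex)
  d$.y <- outcome
  summary(stats::lm(.y ~ ., data = d))$r.squared
}
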