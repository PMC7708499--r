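# Dyadic biography-effect models.
#
# One row per ordered within-group dyad; the sender's and receiver's early
# life attributes are combined into 4-level sender->receiver categories
# (origin, predominant infant housing condition, sex). Five linear mixed
# models -- one per interaction index plus their sum -- test whether these
# categories predict the dyadic indices, with group and sender-within-group
# as random intercepts.

.combo_levels <- list(
  origin = c("captive->captive", "wild->wild", "wild->captive",
             "captive->wild"),
  phc_infant = c("with->with", "without->without", "with->without",
                 "without->with"),
  sex = c("F->F", "M->M", "M->F", "F->M")
)

#' Sender-receiver category label
#'
#' @param sender_attr,receiver_attr Attribute values (e.g. `"wild"`,
#'   `"captive"`) of sender and receiver.
#' @param factor_name `"origin"`, `"phc_infant"` or `"sex"`.
#' @return The `"sender->receiver"` category string.
#' @examples
#' combo_label("wild", "captive", "origin")
#' @export
combo_label <- function(sender_attr, receiver_attr, factor_name) {
  if (!factor_name %in% names(.combo_levels)) {
    stop("unknown factor: ", factor_name, call. = FALSE)
  }
  lab <- paste0(sender_attr, "->", receiver_attr)
  bad <- !lab %in% .combo_levels[[factor_name]]
  if (any(bad)) {
    stop("unknown attribute combination(s) for ", factor_name, ": ",
         paste(unique(lab[bad]), collapse = ", "), call. = FALSE)
  }
  lab
}

#' Build the directed-dyad model table
#'
#' Joins the index table with the roster into one row per ordered
#' within-group dyad, carrying the three sender->receiver category factors,
#' the four interaction indices in wide form, and their sum (`aggregated`).
#' Reference levels are captive->captive, with->with and F->F.
#'
#' @param roster Roster data frame.
#' @param index_table A `dyad_index_table` covering every roster group.
#' @return Data frame with `N * (N - 1)` rows per group.
#' @export
build_dyad_table <- function(roster, index_table) {
  wide <- stats::reshape(
    as.data.frame(index_table)[, c("group", "sender", "receiver", "layer",
                                   "index")],
    idvar = c("group", "sender", "receiver"), timevar = "layer",
    direction = "wide")
  names(wide) <- sub("^index\\.", "", names(wide))
  missing_layers <- setdiff(.layer_names, names(wide))
  if (length(missing_layers) > 0L) {
    stop("index table lacks layer(s): ",
         paste(missing_layers, collapse = ", "), call. = FALSE)
  }
  srow <- match(wide$sender, roster$id)
  rrow <- match(wide$receiver, roster$id)
  if (anyNA(srow) || anyNA(rrow)) {
    stop("index table contains individuals absent from the roster",
         call. = FALSE)
  }
  for (g in unique(roster$group)) {
    n_g <- sum(roster$group == g)
    got <- sum(wide$group == g)
    if (got != n_g * (n_g - 1L)) {
      stop("group ", g, " has ", got, " dyad rows; expected ",
           n_g * (n_g - 1L), call. = FALSE)
    }
  }
  out <- data.frame(
    group = wide$group, sender = wide$sender, receiver = wide$receiver,
    origin_combo = factor(combo_label(as.character(roster$origin[srow]),
                                      as.character(roster$origin[rrow]),
                                      "origin"),
                          levels = .combo_levels$origin),
    phc_combo = factor(combo_label(as.character(roster$phc_infant[srow]),
                                   as.character(roster$phc_infant[rrow]),
                                   "phc_infant"),
                       levels = .combo_levels$phc_infant),
    sex_combo = factor(combo_label(as.character(roster$sex[srow]),
                                   as.character(roster$sex[rrow]), "sex"),
                       levels = .combo_levels$sex),
    stringsAsFactors = FALSE)
  for (l in .layer_names) out[[l]] <- wide[[l]]
  out$aggregated <- rowSums(wide[, .layer_names])
  out
}

.model_responses <- c(.layer_names, "aggregated")

#' Fit the biography-effect mixed model for one response
#'
#' Fits the full linear mixed model
#' `response ~ origin_combo + phc_combo + sex_combo + (1 | group/sender)`
#' and the corresponding intercept-only null model. The full-vs-null
#' comparison is a likelihood-ratio test on maximum-likelihood fits; marginal
#' fixed-effect tests are Type III F tests with Satterthwaite degrees of
#' freedom on the REML fit. Singular random-effect fits are flagged, never
#' silently simplified; factor levels absent from the data are dropped with a
#' warning.
#'
#' @param dyad_table Table from [build_dyad_table()] (>= 2 groups of >= 3
#'   individuals).
#' @param response One of the four layer names or `"aggregated"`.
#' @return A `dyad_model` object: list with `response`, `lrt`
#'   (chisq, df, p), `anova` (Type III table), `vif`, `singular`,
#'   `degenerate`, and the fitted `model` (REML).
#' @export
fit_models <- function(dyad_table, response = .model_responses) {
  response <- match.arg(response)
  for (g in unique(dyad_table$group)) {
    n_g <- length(unique(dyad_table$sender[dyad_table$group == g]))
    if (n_g < 3L) stop("group ", g, " has fewer than 3 individuals; random ",
                       "effects would be singular by construction",
                       call. = FALSE)
  }
  if (length(unique(dyad_table$group)) < 2L) {
    stop("at least two groups are required", call. = FALSE)
  }
  dat <- dyad_table
  dat$.y <- dat[[response]]
  if (stats::var(dat$.y) == 0) {
    warning("response '", response, "' is constant; model fit is degenerate",
            call. = FALSE)
    return(structure(list(response = response, degenerate = TRUE,
                          lrt = list(chisq = 0, df = NA_integer_, p = 1),
                          anova = NULL, vif = NULL, singular = TRUE,
                          model = NULL),
                     class = "dyad_model"))
  }
  factors <- c("origin_combo", "phc_combo", "sex_combo")
  for (f in factors) {
    present <- levels(droplevels(dat[[f]]))
    if (length(present) < nlevels(dat[[f]])) {
      warning("factor ", f, " has unobserved level(s) ",
              paste(setdiff(levels(dat[[f]]), present), collapse = ", "),
              "; dropping", call. = FALSE)
      dat[[f]] <- droplevels(dat[[f]])
    }
  }
  full_f <- stats::as.formula(
    ".y ~ origin_combo + phc_combo + sex_combo + (1 | group/sender)")
  null_f <- stats::as.formula(".y ~ 1 + (1 | group/sender)")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  full_ml <- lme4::lmer(full_f, data = dat, REML = FALSE, control = ctrl)
  null_ml <- lme4::lmer(null_f, data = dat, REML = FALSE, control = ctrl)
  lrt_tab <- stats::anova(null_ml, full_ml)
  full_reml <- lmerTest::lmer(full_f, data = dat, REML = TRUE, control = ctrl)
  a3 <- stats::anova(full_reml, type = 3, ddf = "Satterthwaite")
  vif <- tryCatch(vif_check(dat, response = response),
                  error = function(e) NULL)
  structure(list(
    response = response, degenerate = FALSE,
    lrt = list(chisq = lrt_tab$Chisq[2L], df = lrt_tab$Df[2L],
               p = lrt_tab$`Pr(>Chisq)`[2L]),
    deviance = c(full = stats::deviance(full_ml),
                 null = stats::deviance(null_ml)),
    anova = a3, vif = vif,
    singular = lme4::isSingular(full_reml),
    converged = length(full_reml@optinfo$conv$lme4$messages) == 0L,
    model = full_reml, data = dat),
    class = "dyad_model")
}

#' @export
print.dyad_model <- function(x, ...) {
  cat("dyadic biography-effect model: response =", x$response, "\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate fit (constant response)\n")
    return(invisible(x))
  }
  cat(sprintf("  full vs null: chisq = %.3f, df = %d, p = %.4g\n",
              x$lrt$chisq, x$lrt$df, x$lrt$p))
  cat("  Type III (Satterthwaite) F tests:\n")
  print(round(as.data.frame(x$anova), 4))
  if (x$singular) cat("  note: singular random-effect fit\n")
  invisible(x)
}

#' Post hoc Tukey contrasts with Holm-Bonferroni adjustment
#'
#' All pairwise contrasts between the levels of one sender->receiver factor
#' of a fitted full model, adjusted within the factor's contrast family by
#' the step-down Holm-Bonferroni method.
#'
#' @param fit A `dyad_model` from [fit_models()].
#' @param factor_name `"origin_combo"`, `"phc_combo"` or `"sex_combo"`.
#' @return Data frame with `contrast`, `estimate`, `se`, `z`, `p_raw`,
#'   `p_adj` (one row per level pair).
#' @export
posthoc_contrasts <- function(fit, factor_name) {
  if (isTRUE(fit$degenerate)) stop("cannot compute contrasts of a degenerate ",
                                   "fit", call. = FALSE)
  if (!factor_name %in% c("origin_combo", "phc_combo", "sex_combo")) {
    stop("unknown factor: ", factor_name, call. = FALSE)
  }
  spec <- list("Tukey")
  names(spec) <- factor_name
  glht_fit <- multcomp::glht(fit$model,
                             linfct = do.call(multcomp::mcp, spec))
  raw <- summary(glht_fit, test = multcomp::adjusted("none"))
  adj <- summary(glht_fit, test = multcomp::adjusted("holm"))
  data.frame(
    contrast = names(raw$test$coefficients),
    estimate = unname(raw$test$coefficients),
    se = unname(raw$test$sigma),
    z = unname(raw$test$tstat),
    p_raw = unname(raw$test$pvalues),
    p_adj = unname(adj$test$pvalues),
    stringsAsFactors = FALSE)
}

#' Generalized variance inflation factors of the dyadic fixed design
#'
#' Collinearity diagnostic for the three category factors, computed on the
#' fixed-effects design and reported as `GVIF^(1/(2 df))` squared so values
#' are comparable to conventional VIF thresholds.
#'
#' @param dyad_table Table from [build_dyad_table()].
#' @param response Response column used for the auxiliary linear fit (does
#'   not affect the design collinearity).
#' @return Named numeric vector, one value per factor.
#' @export
vif_check <- function(dyad_table, response = "aggregated") {
  dat <- dyad_table
  dat$.y <- dat[[response]]
  factors <- c("origin_combo", "phc_combo", "sex_combo")
  for (f in factors) dat[[f]] <- droplevels(dat[[f]])
  X <- stats::model.matrix(~ origin_combo + phc_combo + sex_combo, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("aliased fixed-effect design; redundant column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  lm_fit <- stats::lm(.y ~ origin_combo + phc_combo + sex_combo, data = dat)
  v <- car::vif(lm_fit)
  if (is.matrix(v)) {
    out <- v[, "GVIF^(1/(2*Df))"]^2
    names(out) <- rownames(v)
  } else {
    out <- v
  }
  out
}

#' Run all five biography-effect models
#'
#' @param dyad_table Table from [build_dyad_table()].
#' @param alpha Significance level for reporting which full models improve on
#'   their null models.
#' @return Named list of `dyad_model` objects (four layers + aggregated).
#' @export
fit_all_models <- function(dyad_table, alpha = 0.05) {
  fits <- lapply(.model_responses, function(r) fit_models(dyad_table, r))
  names(fits) <- .model_responses
  attr(fits, "improved") <- vapply(
    fits, function(f) !isTRUE(f$degenerate) && f$lrt$p < alpha, logical(1))
  fits
}
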