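#' Construct a linear epigenetic clock model
#'
#' @param name model name.
#' @param intercept intercept in years (or transformed units if
#'   `age_transform = "log_linear_under_20"`).
#' @param coef named numeric vector probe id -> weight.
#' @param train_means optional named numeric vector of training-set probe
#'   means, used to impute missing probes at prediction time.
#' @param age_transform `"identity"` or `"log_linear_under_20"` (the
#'   log-linear-below-20 transform used by multi-tissue clocks).
#' @return object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coef, train_means = NULL,
                        age_transform = c("identity", "log_linear_under_20")) {
  age_transform <- match.arg(age_transform)
  if (!length(coef)) stop("clock needs at least one coefficient")
  if (any(!is.finite(coef)) || !is.finite(intercept))
    stop("weights must be finite")
  structure(list(name = name, intercept = intercept, coef = coef,
                 train_means = train_means, age_transform = age_transform),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Epigenetic clock '", x$name, "': ", length(x$coef),
      " probes, intercept ", round(x$intercept, 3), "\n", sep = "")
  invisible(x)
}

# inverse of the log-linear-under-20 age transform (adult age = 20)
inv_age_transform <- function(y, adult_age = 20) {
  ifelse(y < 0, (1 + adult_age) * exp(y) - 1,
         (1 + adult_age) * y + adult_age)
}

#' Predict epigenetic age from methylation
#'
#' Linear prediction `intercept + sum(weight * beta)` over the model's
#' probes. Missing probes are imputed with the model's training means when
#' available, else with cohort means; an error is raised if fewer than half
#' of the model probes are present.
#'
#' @param model a [clock_model()].
#' @param meth probes x samples beta matrix.
#' @return named numeric vector of predicted ages (years).
#' @export
apply_clock <- function(model, meth) {
  probes <- names(model$coef)
  present <- probes[probes %in% rownames(meth)]
  if (!length(present)) stop("no overlapping probes between model and matrix")
  if (length(present) < 0.5 * length(probes))
    stop("fewer than 50% of model probes present (",
         length(present), "/", length(probes), ")")
  missing <- setdiff(probes, present)
  B <- meth[present, , drop = FALSE]
  pred <- model$intercept + as.numeric(crossprod(B, model$coef[present]))
  if (length(missing)) {
    fill <- if (!is.null(model$train_means) &&
                all(missing %in% names(model$train_means))) {
      model$train_means[missing]
    } else {
      message(length(missing), " model probes missing; imputed with cohort means")
      rep(mean(B), length(missing))
    }
    pred <- pred + sum(model$coef[missing] * fill)
  }
  if (model$age_transform == "log_linear_under_20")
    pred <- inv_age_transform(pred)
  names(pred) <- colnames(meth)
  pred
}

#' Train a ridge-regression epigenetic clock
#'
#' Ridge regression (glmnet, alpha = 0) of chronological age on standardized
#' probe beta values — a practical stand-in for BLUP-type clocks, whose
#' shrinkage is likewise ridge with the penalty tied to the signal-to-noise
#' ratio. The penalty is chosen on a held-out validation fold unless given.
#'
#' @param meth probes x samples beta matrix (training data).
#' @param ages chronological ages aligned with columns.
#' @param ridge_penalty optional fixed lambda; when `NULL` a path is fitted
#'   and the lambda minimizing held-out MSE is chosen.
#' @param val_frac fraction of samples held out for penalty selection
#'   (default 0.2).
#' @param seed integer seed for the validation split.
#' @param name model name.
#' @return a [clock_model()] with training means recorded.
#' @export
train_clock <- function(meth, ages, ridge_penalty = NULL, val_frac = 0.2,
                        seed = 1L, name = "ridge_clock") {
  n <- ncol(meth)
  if (n < 50) stop("need at least 50 training samples")
  if (stats::var(ages) == 0) stop("age vector is constant")
  X <- t(meth)
  if (is.null(ridge_penalty)) {
    set.seed(child_seed(seed, 41L))
    val <- sample.int(n, max(2L, round(val_frac * n)))
    fit <- glmnet::glmnet(X[-val, , drop = FALSE], ages[-val], alpha = 0,
                          standardize = TRUE)
    pred <- stats::predict(fit, X[val, , drop = FALSE])
    mse <- colMeans((pred - ages[val])^2)
    ridge_penalty <- fit$lambda[which.min(mse)]
  }
  fit <- glmnet::glmnet(X, ages, alpha = 0, standardize = TRUE,
                        lambda = ridge_penalty)
  co <- as.numeric(stats::coef(fit))
  clock_model(name, intercept = co[1],
              coef = stats::setNames(co[-1], rownames(meth)),
              train_means = rowMeans(meth))
}

#' Age-acceleration residuals with IQR outlier flagging
#'
#' AAR is predicted minus chronological age. Records outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are flagged as outliers (quartiles by the
#' linear-interpolation definition, computed within group) and excluded from
#' downstream tests.
#'
#' @param predicted predicted epigenetic ages (years).
#' @param chronological chronological ages (years).
#' @param grouping group labels aligned with the ages.
#' @param sample_id optional ids (default names of `predicted` or indices).
#' @return data.frame of class `aar_records`: sample_id, predicted_age,
#'   chronological_age, aar, group, outlier.
#' @export
compute_aar <- function(predicted, chronological, grouping,
                        sample_id = NULL) {
  n <- length(predicted)
  stopifnot(length(chronological) == n, length(grouping) == n)
  if (is.null(sample_id))
    sample_id <- names(predicted) %||% as.character(seq_len(n))
  aar <- predicted - chronological
  outlier <- logical(n)
  for (g in unique(grouping)) {
    ix <- which(grouping == g)
    if (length(ix) < 4) {
      warning("group ", g, " has fewer than 4 records; no outlier filtering")
      next
    }
    q <- stats::quantile(aar[ix], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    outlier[ix] <- aar[ix] < q[1] - 1.5 * iqr | aar[ix] > q[2] + 1.5 * iqr
  }
  out <- data.frame(sample_id = sample_id, predicted_age = predicted,
                    chronological_age = chronological, aar = aar,
                    group = as.character(grouping), outlier = outlier,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("aar_records", "data.frame")
  out
}

#' Group comparisons of age-acceleration residuals
#'
#' Kruskal--Wallis omnibus test across groups plus pairwise two-sample
#' Wilcoxon rank-sum tests (the groups are independent samples) and mean
#' AAR differences in years, on non-outlier records.
#'
#' @param aar an `aar_records` data.frame from [compute_aar()].
#' @return list: `kruskal_p`, `pairwise` (data.frame: group1, group2,
#'   wilcox_p, mean_diff), `group_means`.
#' @export
group_aar_tests <- function(aar) {
  keep <- aar[!aar$outlier, , drop = FALSE]
  groups <- unique(keep$group)
  sizes <- table(keep$group)
  if (length(groups) < 2 || any(sizes < 3))
    stop("need >= 2 groups with >= 3 non-outlier records each")
  kw <- stats::kruskal.test(keep$aar, factor(keep$group))
  pairs <- utils::combn(sort(groups), 2)
  pw <- apply(pairs, 2, function(gg) {
    x <- keep$aar[keep$group == gg[1]]
    y <- keep$aar[keep$group == gg[2]]
    data.frame(group1 = gg[1], group2 = gg[2],
               wilcox_p = stats::wilcox.test(x, y)$p.value,
               mean_diff = mean(x) - mean(y), stringsAsFactors = FALSE)
  })
  list(kruskal_p = kw$p.value, pairwise = do.call(rbind, pw),
       group_means = tapply(keep$aar, keep$group, mean))
}

#' Phenotype-category association with age acceleration
#'
#' Within one group, RINT-transforms each phenotype, then tests each
#' category of phenotypes jointly by an F test of
#' `AAR ~ age + age^2 + category phenotypes` against the covariate-only
#' model `AAR ~ age + age^2`. Significance is conventionally assessed at
#' a Bonferroni level of alpha / number of categories (0.05/8 for the
#' eight questionnaire/blood categories).
#'
#' @param aar an `aar_records` data.frame (non-outliers used).
#' @param phenotypes data.frame of numeric phenotypes, rows aligned with
#'   `aar` rows.
#' @param category_map named list category -> character vector of phenotype
#'   column names.
#' @param group group label to analyse within.
#' @return data.frame: category, n_phenotypes, f_stat, p; categories whose
#'   phenotypes are entirely missing are skipped with a message.
#' @export
category_association <- function(aar, phenotypes, category_map, group) {
  sel <- aar$group == group & !aar$outlier
  y <- aar$aar[sel]
  age <- aar$chronological_age[sel]
  ph <- phenotypes[sel, , drop = FALSE]
  rows <- lapply(names(category_map), function(cat) {
    cols <- intersect(category_map[[cat]], colnames(ph))
    cols <- cols[vapply(cols, function(cc) !all(is.na(ph[[cc]])), logical(1))]
    if (!length(cols)) {
      message("category '", cat, "' has no usable phenotypes; skipped")
      return(NULL)
    }
    Z <- vapply(cols, function(cc) rint(ph[[cc]]), numeric(sum(sel)))
    cc_ok <- stats::complete.cases(Z, y, age)
    base <- stats::lm(y ~ age + I(age^2), subset = cc_ok)
    full <- stats::lm(y ~ age + I(age^2) + Z, subset = cc_ok)
    an <- stats::anova(base, full)
    data.frame(category = cat, n_phenotypes = length(cols),
               f_stat = an$F[2], p = an$`Pr(>F)`[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Prediction accuracy as squared correlation
#'
#' The reported accuracy convention is the squared Pearson correlation
#' between predicted and chronological age (so a sign-flipped predictor
#' still scores 1); `1 - SSE/SST` is available via `definition`.
#'
#' @param predicted,chronological aligned age vectors (n >= 3).
#' @param definition `"cor2"` (default) or `"ss"`.
#' @return R-squared.
#' @export
r2_accuracy <- function(predicted, chronological,
                        definition = c("cor2", "ss")) {
  definition <- match.arg(definition)
  if (length(predicted) < 3) stop("need at least 3 samples")
  if (definition == "cor2") {
    stats::cor(predicted, chronological)^2
  } else {
    1 - sum((chronological - predicted)^2) /
      sum((chronological - mean(chronological))^2)
  }
}

#' Read / write clock coefficient files
#'
#' JSON schema: `{name, intercept, coef: {probe: weight}, train_means:
#' {probe: mean}, age_transform}`. `train_means` and `age_transform` are
#' optional.
#'
#' @param path file path.
#' @return for the reader, a [clock_model()].
#' @export
read_clock_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  clock_model(name = j$name, intercept = j$intercept,
              coef = unlist(j$coef),
              train_means = if (!is.null(j$train_means)) unlist(j$train_means),
              age_transform = j$age_transform %||% "identity")
}

#' @rdname read_clock_json
#' @param model a [clock_model()] to serialize.
#' @export
write_clock_json <- function(model, path) {
  jsonlite::write_json(
    list(name = model$name, intercept = model$intercept,
         coef = as.list(model$coef),
         train_means = if (!is.null(model$train_means))
           as.list(model$train_means),
         age_transform = model$age_transform),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
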