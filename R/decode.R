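#' Centre and scale a numeric vector
#'
#' Standardizes to sample mean 0 and SD 1 over the non-missing entries;
#' missing values propagate. Both the eigenbrain weights and continuous
#' dependent variables are standardized this way before regression, so
#' coefficients read as SD-per-SD effects.
#'
#' @param x Numeric vector with at least 2 non-missing values.
#' @return The standardized vector, with attributes `center` and `scale`.
#' @export
standardize_columns <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric")
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  if (s == 0) stop("constant variable: standard deviation is zero")
  out <- (x - m) / s
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

# Standardize each column of a weight matrix over given rows.
std_weight_matrix <- function(W, rows) {
  Ws <- apply(W[rows, , drop = FALSE], 2L, standardize_columns)
  matrix(as.numeric(Ws), nrow = sum(rows),
         dimnames = list(NULL, colnames(W)))
}

eb_names <- function(W) {
  cn <- colnames(W)
  if (is.null(cn)) cn <- paste0("EB", seq_len(ncol(W)))
  cn
}

#' Linear decoding of a continuous clinical variable
#'
#' Ordinary least squares of the standardized variable on all k standardized
#' eigenbrain weights jointly (listwise deletion). Coefficients are fully
#' standardized (SD change in y per SD change in weight); the omnibus test is
#' the overall F-test.
#'
#' @param y Numeric vector, one value per participant (NA allowed).
#' @param W Weight matrix, subjects x k (e.g. `coef(fit)`).
#' @param name Variable name used in messages and results.
#' @return List with `kind`, `variable`, `n`, `estimate` (standardized betas),
#'   `p_coef`, `r_squared`, `adj_r_squared`, `p_omnibus`.
#' @export
fit_continuous <- function(y, W, name = "y") {
  W <- as.matrix(W)
  k <- ncol(W)
  cc <- stats::complete.cases(y, W)
  n <- sum(cc)
  if (n < k + 2L)
    stop(sprintf("variable '%s': %d complete cases; need at least %d for %d components",
                 name, n, k + 2L, k))
  ys <- standardize_columns(y[cc])
  Ws <- std_weight_matrix(W, cc)
  d <- data.frame(.y = as.numeric(ys), Ws, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = d)
  sm <- summary(fit)
  beta <- stats::coef(fit)[-1L]
  pc <- sm$coefficients[-1L, 4L]
  names(beta) <- names(pc) <- eb_names(W)
  fstat <- sm$fstatistic
  list(kind = "continuous", variable = name, n = n,
       estimate = beta, p_coef = pc,
       r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
       p_omnibus = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                    lower.tail = FALSE)))
}

#' Logistic decoding of a binary clinical variable
#'
#' Maximum-likelihood logistic regression of a present/absent variable on all
#' k standardized eigenbrain weights. Exponentiated coefficients are odds
#' ratios per SD of weight; the omnibus test is the likelihood-ratio test
#' against the intercept-only model. Complete separation is detected and
#' flagged rather than silently returning diverged estimates.
#'
#' @inheritParams fit_continuous
#' @param y Binary variable: logical, factor, character or 0/1 numeric.
#' @param level The modelled ("present") level; default: the alphabetically
#'   last level, recorded in the result.
#' @return List with `kind`, `variable`, `n`, `estimate` (odds ratios per SD),
#'   `p_coef` (Wald), `p_omnibus` (LRT), `modelled_level`, `separation`.
#' @export
fit_binary <- function(y, W, name = "y", level = NULL) {
  W <- as.matrix(W)
  k <- ncol(W)
  if (is.logical(y)) y <- ifelse(y, "TRUE", "FALSE")
  if (is.numeric(y)) y <- as.character(y)
  y <- as.character(y)
  cc <- !is.na(y) & stats::complete.cases(W)
  n <- sum(cc)
  if (n < k + 2L)
    stop(sprintf("variable '%s': %d complete cases; need at least %d for %d components",
                 name, n, k + 2L, k))
  lev <- sort(unique(y[cc]))
  if (length(lev) < 2L)
    stop(sprintf("variable '%s': degenerate outcome, only one level present", name))
  if (length(lev) > 2L)
    stop(sprintf("variable '%s': %d levels; binary decoding needs exactly 2",
                 name, length(lev)))
  if (is.null(level)) level <- lev[length(lev)]
  if (!level %in% lev)
    stop(sprintf("variable '%s': modelled level '%s' not present", name, level))
  yb <- as.integer(y[cc] == level)
  Ws <- std_weight_matrix(W, cc)
  d <- data.frame(.y = yb, Ws, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  eps <- 1e-8
  separation <- sep_warn || any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  sm <- summary(fit)
  or <- exp(stats::coef(fit)[-1L])
  pc <- sm$coefficients[-1L, 4L]
  names(or) <- names(pc) <- eb_names(W)
  p_omni <- stats::pchisq(fit$null.deviance - fit$deviance,
                          df = fit$df.null - fit$df.residual,
                          lower.tail = FALSE)
  list(kind = "binary", variable = name, n = n,
       estimate = or, p_coef = pc, modelled_level = level,
       separation = separation, p_omnibus = unname(p_omni))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: with the p-values sorted
#' ascending, `q_i = min_{j >= i} p_j * m / j`, capped at 1 and returned in
#' input order. Missing values stay missing and do not count towards `m`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  names(out) <- names(p)
  out
}

#' Decode clinical variables from eigenbrain weights
#'
#' Fits every clinical variable against all retained eigenbrain weights:
#' linear models with fully standardized coefficients for continuous
#' variables, logistic models with per-SD odds ratios for binary ones.
#' Listwise deletion is applied per variable, so `n` varies across rows.
#' The per-variable omnibus p-values form one family to which
#' Benjamini-Hochberg FDR correction is applied; per-coefficient p-values
#' are reported unadjusted with a significance marker at `alpha`.
#' A variable whose fit fails (all missing, one outcome level, too few
#' complete cases) yields a flagged row; the batch continues.
#'
#' @param object A `"bpr"` fit or a subjects x k weight matrix.
#' @param clinical Data frame, one row per participant. Rows are matched to
#'   the weight matrix by an `id` column or by rownames when present,
#'   otherwise taken to be in the same order.
#' @param kinds Optional named character vector mapping variable names to
#'   `"continuous"` or `"binary"`; unnamed variables are inferred (numeric
#'   with more than two distinct values: continuous, otherwise binary).
#'   Defaults to all columns of `clinical` except the id.
#' @param levels Optional named character vector giving the modelled level
#'   for binary variables.
#' @param alpha Significance level for the per-coefficient marker.
#' @return An object of class `"bpr_decode"`: list with `results` (full
#'   per-variable detail), `table` (one row per variable: kind, n, R2,
#'   adjusted R2, per-EB estimate, omnibus p, FDR-adjusted p, note) and
#'   `alpha`.
#' @export
decode <- function(object, clinical, kinds = NULL, levels = NULL,
                   alpha = 0.05) {
  W <- if (inherits(object, "bpr")) stats::coef(object) else as.matrix(object)
  clinical <- as.data.frame(clinical)

  id_col <- intersect(c("id", "ID", "subject_id"), names(clinical))[1L]
  if (!is.na(id_col)) {
    ids <- as.character(clinical[[id_col]])
    if (!is.null(rownames(W))) {
      mi <- match(rownames(W), ids)
      if (anyNA(mi))
        stop("clinical table is missing ids: ",
             paste(utils::head(rownames(W)[is.na(mi)], 5L), collapse = ", "))
      clinical <- clinical[mi, , drop = FALSE]
    } else if (nrow(clinical) != nrow(W)) {
      stop("cannot align clinical table with the weight matrix")
    }
    clinical[[id_col]] <- NULL
  } else if (nrow(clinical) != nrow(W)) {
    stop("clinical table and weight matrix differ in length and share no ids")
  }

  vars <- if (is.null(kinds)) names(clinical) else names(kinds)
  if (length(vars) == 0L) stop("no clinical variables to decode")
  missing_vars <- setdiff(vars, names(clinical))
  if (length(missing_vars))
    stop("variables not in the clinical table: ",
         paste(missing_vars, collapse = ", "))

  infer_kind <- function(v) {
    x <- clinical[[v]]
    if (!is.null(kinds) && !is.na(kinds[v])) return(unname(kinds[v]))
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2L) "continuous" else "binary"
  }

  results <- vector("list", length(vars))
  names(results) <- vars
  for (v in vars) {
    kind <- infer_kind(v)
    results[[v]] <- tryCatch({
      if (kind == "continuous") {
        fit_continuous(clinical[[v]], W, name = v)
      } else {
        lv <- if (!is.null(levels) && !is.na(levels[v])) unname(levels[v]) else NULL
        fit_binary(clinical[[v]], W, name = v, level = lv)
      }
    }, error = function(e) {
      list(kind = kind, variable = v, n = NA_integer_, estimate = NULL,
           p_omnibus = NA_real_, note = conditionMessage(e))
    })
  }

  p_omni <- vapply(results, function(r) r$p_omnibus, numeric(1L))
  p_fdr <- fdr_bh(p_omni)
  for (v in vars) results[[v]]$p_fdr <- p_fdr[[v]]

  cn <- eb_names(W)
  est <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$estimate)) rep(NA_real_, length(cn)) else unname(r$estimate)
  }))
  colnames(est) <- cn
  tab <- data.frame(
    variable = vars,
    kind = vapply(results, `[[`, character(1L), "kind"),
    n = vapply(results, function(r) as.integer(r$n), integer(1L)),
    r_squared = vapply(results, function(r)
      if (is.null(r$r_squared)) NA_real_ else r$r_squared, numeric(1L)),
    adj_r_squared = vapply(results, function(r)
      if (is.null(r$adj_r_squared)) NA_real_ else r$adj_r_squared, numeric(1L)),
    est,
    p_omnibus = p_omni,
    p_fdr = p_fdr,
    note = vapply(results, function(r)
      if (is.null(r$note)) "" else r$note, character(1L)),
    row.names = NULL, check.names = FALSE
  )
  structure(list(results = results, table = tab, alpha = alpha, k = length(cn)),
            class = "bpr_decode")
}

#' @export
as.data.frame.bpr_decode <- function(x, ...) x$table

#' @export
print.bpr_decode <- function(x, digits = 3, ...) {
  tab <- x$table
  cat(sprintf("Clinical decoding over %d eigenbrains, %d variables (alpha = %g)\n",
              x$k, nrow(tab), x$alpha))
  cat("Continuous rows: standardized betas; binary rows: odds ratios per SD.\n")
  cat("'*' marks per-coefficient p <", x$alpha,
      "; omnibus p FDR-adjusted across variables.\n\n")
  cn <- setdiff(names(tab), c("variable", "kind", "n", "r_squared",
                              "adj_r_squared", "p_omnibus", "p_fdr", "note"))
  out <- tab[, c("variable", "kind", "n")]
  for (j in cn) {
    col <- formatC(tab[[j]], digits = digits, format = "fg")
    mark <- vapply(seq_len(nrow(tab)), function(i) {
      r <- x$results[[tab$variable[i]]]
      !is.null(r$p_coef) && !is.na(r$p_coef[j]) && r$p_coef[j] < x$alpha
    }, logical(1L))
    out[[j]] <- paste0(col, ifelse(mark, "*", ""))
  }
  out$p <- format.pval(tab$p_omnibus, digits = digits)
  out$p_fdr <- format.pval(tab$p_fdr, digits = digits)
  flagged <- nzchar(tab$note)
  if (any(flagged)) out[flagged, cn] <- "--"
  print(out, row.names = FALSE)
  if (any(flagged)) {
    cat("\nFlagged variables:\n")
    for (i in which(flagged))
      cat(" ", tab$variable[i], ":", tab$note[i], "\n")
  }
  sep <- vapply(x$results, function(r) isTRUE(r$separation), logical(1L))
  if (any(sep))
    cat("\nSeparation detected for:",
        paste(names(sep)[sep], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bpr_decode <- function(object, ...) {
  tab <- object$table
  cat(sprintf("%d variables decoded; %d flagged; %d significant after FDR (q < %g)\n",
              nrow(tab), sum(nzchar(tab$note)),
              sum(tab$p_fdr < object$alpha, na.rm = TRUE), object$alpha))
  invisible(object$table)
}
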