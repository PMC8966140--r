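#' Mixed ANOVA with a between-participants group factor and a
#' within-participants environment factor
#'
#' Fits a repeated-measures ANOVA (Type III sums of squares on a
#' multivariate linear model) with one between factor and one within
#' factor, applying the Greenhouse-Geisser correction to the
#' within-involving effects when Mauchly's test rejects sphericity.
#' Participants missing more than half of the environments are excluded
#' with a warning; remaining incomplete participants are dropped listwise.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param between,within,subject column names of the between factor, the
#'   within factor and the subject identifier.
#' @param sphericity_alpha Mauchly-test level below which the correction is
#'   applied (default 0.05).
#' @return data.frame of class `anova_results` with one row per effect
#'   (between main effect, within main effect, interaction): `factor`,
#'   `measure`, `F`, `df1`, `df2` (non-integer after correction), `p`,
#'   `p_adj` (`NA` until [bh_adjust()] is applied across a family),
#'   `effect_size` (partial eta squared), `gg_applied`, `mauchly_p`.
#' @export
mixed_anova <- function(data, dv, between = "group", within = "environment",
                        subject = "participant_id",
                        sphericity_alpha = 0.05) {
  stopifnot(all(c(dv, between, within, subject) %in% names(data)))
  d <- data.frame(subj = factor(data[[subject]]),
                  grp = factor(data[[between]]),
                  w = factor(data[[within]]),
                  y = as.numeric(data[[dv]]))
  d <- d[!is.na(d$y), ]
  n_env <- nlevels(d$w)
  cnt <- table(d$subj)
  few <- names(cnt)[cnt < n_env / 2]
  if (length(few)) {
    warning(length(few), " participant(s) missing > 50% of environments excluded for ", dv)
    d <- d[!(d$subj %in% few), ]
    d$subj <- droplevels(d$subj)
  }
  incomplete <- names(table(d$subj))[table(d$subj) < n_env]
  if (length(incomplete)) {
    warning(length(incomplete), " incomplete participant(s) dropped listwise for ", dv)
    d <- d[!(d$subj %in% incomplete), ]
  }
  d$subj <- droplevels(d$subj); d$grp <- droplevels(d$grp)
  res_row <- function(fac, F, df1, df2, p, pes, gg, mp) {
    data.frame(factor = fac, measure = dv, F = F, df1 = df1, df2 = df2,
               p = p, p_adj = NA_real_, effect_size = pes,
               gg_applied = gg, mauchly_p = mp, stringsAsFactors = FALSE)
  }
  if (stats::sd(d$y) < 1e-12) {
    out <- rbind(res_row("group", 0, nlevels(d$grp) - 1,
                         nlevels(d$subj) - nlevels(d$grp), 1, 0, FALSE, NA),
                 res_row("environment", 0, n_env - 1, NA, 1, 0, FALSE, NA),
                 res_row("group:environment", 0, NA, NA, 1, 0, FALSE, NA))
    class(out) <- c("anova_results", class(out))
    return(out)
  }
  wide <- stats::reshape(d, idvar = c("subj", "grp"), timevar = "w",
                         direction = "wide")
  ycols <- grep("^y\\.", names(wide))
  Y <- as.matrix(wide[, ycols])
  grp <- wide$grp
  fit <- stats::lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
  idata <- data.frame(w = factor(sub("^y\\.", "", names(wide)[ycols]),
                                 levels = sub("^y\\.", "", names(wide)[ycols])))
  an <- car::Anova(fit, idata = idata, idesign = ~w, type = 3)
  s <- suppressWarnings(summary(an, multivariate = FALSE))
  u <- s$univariate.tests
  mauchly <- s$sphericity.tests
  adj <- s$pval.adjustments
  get_row <- function(name, label, within_involved) {
    ss <- u[name, "Sum Sq"]; ess <- u[name, "Error SS"]
    df1 <- u[name, "num Df"]; df2 <- u[name, "den Df"]
    F <- u[name, "F value"]; p <- u[name, "Pr(>F)"]
    pes <- ss / (ss + ess)
    gg <- FALSE; mp <- NA_real_
    if (within_involved && name %in% rownames(mauchly)) {
      mp <- mauchly[name, "p-value"]
      if (is.finite(mp) && mp < sphericity_alpha && name %in% rownames(adj)) {
        eps <- adj[name, "GG eps"]
        df1 <- df1 * eps; df2 <- df2 * eps
        p <- adj[name, "Pr(>F[GG])"]
        gg <- TRUE
      }
    }
    res_row(label, F, df1, df2, p, pes, gg, mp)
  }
  out <- rbind(
    get_row("grp", "group", FALSE),
    get_row("w", "environment", TRUE),
    get_row("grp:w", "group:environment", TRUE)
  )
  rownames(out) <- NULL
  class(out) <- c("anova_results", class(out))
  out
}

#' Benjamini-Hochberg adjustment of a p-value family
#'
#' Standard step-up false-discovery-rate adjustment, monotone and capped
#' at 1. Intended to be applied once across the grouped results of all
#' ANOVAs run in one pipeline invocation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value family")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise group comparisons per environment with Bonferroni correction
#'
#' Welch two-sample t-tests between all group pairs within each
#' environment; raw p-values are multiplied by the number of comparisons
#' performed in that environment and capped at 1.
#'
#' @param data long-format data.frame.
#' @param dv dependent-variable column name.
#' @param group,by group and environment column names.
#' @return data.frame with columns `environment`, `group1`, `group2`,
#'   `mean_diff`, `p`, `p_adj`, `m` (family size).
#' @export
pairwise_bonferroni <- function(data, dv, group = "group",
                                by = "environment") {
  stopifnot(all(c(dv, group, by) %in% names(data)))
  out <- list()
  for (env in unique(data[[by]])) {
    d <- data[data[[by]] == env & !is.na(data[[dv]]), ]
    gs <- unique(as.character(d[[group]]))
    sizes <- vapply(gs, function(g) sum(d[[group]] == g), 0L)
    if (any(sizes < 2)) {
      warning("group(s) with n < 2 skipped in ", env, ": ",
              paste(gs[sizes < 2], collapse = ", "))
      gs <- gs[sizes >= 2]
    }
    if (length(gs) < 2) next
    pairs <- utils::combn(sort(gs), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      x <- d[[dv]][d[[group]] == pairs[1, k]]
      y <- d[[dv]][d[[group]] == pairs[2, k]]
      tt <- stats::t.test(x, y)
      data.frame(environment = env, group1 = pairs[1, k],
                 group2 = pairs[2, k], mean_diff = mean(x) - mean(y),
                 p = tt$p.value, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$p_adj <- pmin(1, fam$p * nrow(fam))
    fam$m <- nrow(fam)
    out[[length(out) + 1]] <- fam
  }
  if (!length(out))
    return(data.frame(environment = character(0), group1 = character(0),
                      group2 = character(0), mean_diff = numeric(0),
                      p = numeric(0), p_adj = numeric(0), m = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run grouped ANOVAs on a measures table and adjust across the family
#'
#' One mixed ANOVA per dependent variable; the Benjamini-Hochberg
#' adjustment is applied jointly to all main-effect and interaction
#' p-values of the family, mirroring a single analysis pipeline
#' invocation.
#'
#' @param data long or wide measures table (wide: one column per measure).
#' @param dvs character vector of dependent-variable column names.
#' @param ... forwarded to [mixed_anova()].
#' @return `anova_results` data.frame with `p_adj` filled in.
#' @export
grouped_anovas <- function(data, dvs, ...) {
  res <- do.call(rbind, lapply(dvs, function(dv) mixed_anova(data, dv, ...)))
  res$p_adj <- bh_adjust(res$p)
  class(res) <- c("anova_results", "data.frame")
  res
}

#' @export
print.anova_results <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$F <- signif(y$F, digits); y$df1 <- signif(y$df1, digits)
  y$df2 <- signif(y$df2, digits)
  y$p <- signif(y$p, digits); y$p_adj <- signif(y$p_adj, digits)
  y$effect_size <- signif(y$effect_size, 2)
  print.data.frame(y[, c("factor", "measure", "F", "df1", "df2", "p",
                         "p_adj", "effect_size", "gg_applied")],
                   row.names = FALSE)
  invisible(x)
}
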