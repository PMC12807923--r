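## Per-timepoint one-way ANOVA with Tukey HSD and compact-letter displays,
## applied uniformly to diversity indices, EcoPlate indices and gene or
## CAZy/KEGG abundances: the standard "letters over bars" annotation.

#' One-way ANOVA
#'
#' Fixed-effects one-way analysis of variance via \code{stats::aov}:
#' \eqn{F = MS_{between} / MS_{within}} on
#' \eqn{(k - 1, N - k)} degrees of freedom.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor).
#' @return list with \code{F}, \code{p}, \code{df_between},
#'   \code{df_within}.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  assert_that(nlevels(groups) >= 2L, "need at least 2 groups")
  assert_that(all(table(groups) >= 2L), "each group needs >= 2 observations")
  if (stats::var(values) == 0)
    stop2("all values identical: ANOVA is degenerate")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  list(F = tab[1L, "F value"], p = tab[1L, "Pr(>F)"],
       df_between = tab[1L, "Df"], df_within = tab[2L, "Df"])
}

#' Tukey HSD pairwise comparisons
#'
#' Family-wise pairwise p-values from the studentized-range distribution
#' (\code{stats::TukeyHSD} on the one-way fit; Tukey-Kramer for unbalanced
#' groups). With two groups the Tukey p equals the two-sided
#' pooled-variance t-test p (q = t\eqn{\sqrt{2}}).
#'
#' @param values numeric response vector.
#' @param groups group labels.
#' @return symmetric matrix of adjusted p-values with group names on both
#'   dimensions and \code{NA} diagonal.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  assert_that(nlevels(groups) >= 2L, "need at least 2 groups")
  if (stats::var(values) == 0)
    stop2("all values identical: pairwise tests are degenerate")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  lv <- levels(groups)
  p <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    p[a, b] <- p[b, a] <- tk[i, "p adj"]
  }
  p
}

#' Compact letter display
#'
#' Assigns letters to groups so that two groups share a letter if and
#' only if their pairwise test is not significant at \code{alpha}
#' (insert-and-absorb algorithm). Letters start at "a" for the
#' highest-mean group, matching the usual figure annotation.
#'
#' @param pairwise_p symmetric matrix of pairwise p-values (dimnames =
#'   group labels).
#' @param means named numeric vector of group means (orders the letters).
#' @param alpha significance level.
#' @return list of class \code{letter_display}: \code{letters} (named
#'   character vector), \code{alpha}.
#' @export
compact_letters <- function(pairwise_p, means, alpha = 0.05) {
  groups <- rownames(pairwise_p)
  assert_that(!is.null(groups) && identical(groups, colnames(pairwise_p)),
              "pairwise_p needs matching dimnames", class = "schema_error")
  assert_that(all(groups %in% names(means)), "means must name every group")
  ord <- groups[order(-means[groups])]

  ## insert-and-absorb on letter columns (sets of groups that may share)
  cols <- list(ord)
  for (i in seq_along(ord)) {
    for (j in seq_len(i - 1L)) {
      a <- ord[i]; b <- ord[j]
      if (!is.na(pairwise_p[a, b]) && pairwise_p[a, b] < alpha) {
        for (k in seq_along(cols)) {
          if (all(c(a, b) %in% cols[[k]])) {
            cols <- append(cols, list(setdiff(cols[[k]], a)))
            cols[[k]] <- setdiff(cols[[k]], b)
          }
        }
        ## absorb: drop columns that are subsets of another
        keep <- rep(TRUE, length(cols))
        for (k in seq_along(cols)) {
          for (l in seq_along(cols)) {
            if (k != l && keep[l] &&
                all(cols[[k]] %in% cols[[l]]) &&
                (length(cols[[k]]) < length(cols[[l]]) || k > l))
              keep[k] <- FALSE
          }
        }
        cols <- cols[keep]
      }
    }
  }
  ## order columns by the position of their best-ranked member, letter them
  first <- vapply(cols, function(cl) min(match(cl, ord)), numeric(1))
  cols <- cols[order(first)]
  lab <- vapply(ord, function(g) {
    paste(letters[which(vapply(cols, function(cl) g %in% cl, logical(1)))],
          collapse = "")
  }, character(1))
  structure(list(letters = lab[groups], alpha = alpha),
            class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  print(x$letters)
  invisible(x)
}

## Verify the defining property: share a letter <=> not significant.
letters_consistent <- function(display, pairwise_p, alpha = display$alpha) {
  lab <- display$letters
  groups <- names(lab)
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    share <- length(intersect(strsplit(lab[i], "")[[1L]],
                              strsplit(lab[j], "")[[1L]])) > 0L
    sig <- !is.na(pairwise_p[groups[i], groups[j]]) &&
      pairwise_p[groups[i], groups[j]] < alpha
    if (share == sig) return(FALSE)
  }
  TRUE
}

#' Per-timepoint group comparison with letters
#'
#' For each response row of a feature table and each sampling day,
#' performs one-way ANOVA across treatments on the replicate values,
#' pairwise post-hoc tests (Tukey HSD by default, Fisher LSD optionally)
#' and a compact letter display. Reports mean and standard error
#' (sd/sqrt(n)) per cell. Days with any (day, treatment) cell holding
#' fewer than 2 replicates are skipped with a warning; so are degenerate
#' days where all values coincide.
#'
#' @param table an \code{abundance_table} (rows = responses) or a named
#'   list of numeric vectors indexed by sample id.
#' @param design a \code{sample_design}.
#' @param alpha significance level (default 0.05).
#' @param posthoc \code{"tukey"} (default) or \code{"lsd"}.
#' @return long data frame: \code{response}, \code{day}, \code{treatment},
#'   \code{mean}, \code{se}, \code{n}, \code{letters}, \code{F},
#'   \code{p_anova}.
#' @export
compare_by_timepoint <- function(table, design, alpha = 0.05,
                                 posthoc = c("tukey", "lsd")) {
  posthoc <- match.arg(posthoc)
  m <- if (inherits(table, "abundance_table")) table$matrix
       else do.call(rbind, table)
  assert_that(!is.null(rownames(m)), "responses must be named",
              class = "schema_error")
  common <- intersect(colnames(m), design$sample_id)
  des <- design[match(common, design$sample_id), ]
  out <- list()
  for (resp in rownames(m)) {
    for (day in sort(unique(des$day))) {
      sel <- des$day == day
      vals <- m[resp, des$sample_id[sel]]
      grp <- factor(des$treatment[sel])
      if (any(tabulate(grp) < 2L) || nlevels(grp) < 2L) {
        warn2("day ", day, " skipped for ", resp,
              ": needs >= 2 replicates in >= 2 treatments")
        next
      }
      cell_mean <- tapply(vals, grp, mean)
      cell_se <- tapply(vals, grp, function(v) stats::sd(v) / sqrt(length(v)))
      cell_n <- as.integer(tabulate(grp))
      if (stats::var(vals) == 0) {
        lab <- stats::setNames(rep("a", nlevels(grp)), levels(grp))
        Fv <- NA_real_; pv <- NA_real_
      } else {
        an <- one_way_anova(vals, grp)
        pw <- if (posthoc == "tukey") tukey_hsd(vals, grp)
              else .lsd_p(vals, grp)
        cl <- compact_letters(pw, means = cell_mean, alpha = alpha)
        lab <- cl$letters
        Fv <- an$F; pv <- an$p
      }
      out[[length(out) + 1L]] <- data.frame(
        response = resp, day = day, treatment = levels(grp),
        mean = as.numeric(cell_mean), se = as.numeric(cell_se), n = cell_n,
        letters = unname(lab), F = Fv, p_anova = pv,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

## Fisher LSD: unadjusted pairwise t-tests on the pooled within-group MS.
.lsd_p <- function(values, groups) {
  groups <- factor(groups)
  fit <- stats::aov(values ~ groups)
  mse <- summary(fit)[[1L]][2L, "Mean Sq"]
  dfw <- summary(fit)[[1L]][2L, "Df"]
  lv <- levels(groups)
  mns <- tapply(values, groups, mean)
  ns <- table(groups)
  p <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_len(i - 1L)) {
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tt <- abs(mns[i] - mns[j]) / se
    p[i, j] <- p[j, i] <- 2 * stats::pt(tt, dfw, lower.tail = FALSE)
  }
  p
}
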