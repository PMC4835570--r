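# normalization policy used before parametric screens: gas exchange rates are
# log-transformed, bacterial abundance square-root transformed, the rest kept
default_transforms <- function() {
  c(H2 = "log", CO = "log", CO2 = "log", bacteria = "sqrt")
}

apply_transform <- function(x, how) {
  if (is.null(how) || is.na(how)) how <- "identity"
  switch(how,
         log = log(x),
         sqrt = sqrt(x),
         identity = x,
         abort(paste0("unknown transform: ", how), class = "mfsoil_config"))
}

transform_variables <- function(data, variables, transforms) {
  for (v in variables) {
    data[[v]] <- apply_transform(data[[v]], unname(transforms[v]))
  }
  data
}

#' Pairwise Pearson correlations between soil variables
#'
#' Variables are first normalized per policy (log for gas exchanges, square
#' root for bacterial abundance by default); a Shapiro-Wilk normality screen
#' is reported alongside each variable.
#'
#' @param data Biogeochemical tibble.
#' @param variables Variables to correlate.
#' @param transforms Named character vector (`"log"`, `"sqrt"`,
#'   `"identity"`) per variable; unnamed variables are left as is.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble `var1`, `var2`, `r`, `p` for each unordered pair, with a
#'   per-variable Shapiro-Wilk tibble attached as `attr(, "shapiro")`.
#' @export
correlate_variables <- function(data, variables = NULL,
                                transforms = default_transforms(),
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(variables)) variables <- intersect(soil_variables(), names(data))
  data <- transform_variables(data, variables, transforms)
  for (v in variables) {
    if (sd(data[[v]]) == 0) {
      abort(paste0("constant variable: ", v), class = "mfsoil_constant")
    }
  }
  pairs <- utils::combn(variables, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    ct <- cor.test(data[[v1]], data[[v2]], method = method, exact = FALSE)
    tibble(var1 = v1, var2 = v2, r = unname(ct$estimate), p = ct$p.value)
  }) |> bind_rows()
  attr(out, "shapiro") <- purrr::map(variables, function(v) {
    sw <- shapiro.test(data[[v]])
    tibble(variable = v, W = unname(sw$statistic), p = sw$p.value)
  }) |> bind_rows()
  out
}

#' One-way ANOVA screen of soil variables across treatments
#'
#' Per variable (after the configured normalization): Shapiro-Wilk
#' normality check, one-way ANOVA F-test across groups, and pairwise
#' t-tests with Bonferroni-corrected p-values.
#'
#' @param data Biogeochemical tibble.
#' @param groups Grouping vector (e.g. treatment), or the name of a column.
#' @param variables Variables to screen.
#' @param transforms Normalization policy as in [correlate_variables()].
#' @return Tibble `variable`, `F`, `p`, `shapiro_p`, `significant`
#'   (p <= 0.05); pairwise Bonferroni t-test matrices in
#'   `attr(, "posthoc")` (named list).
#' @export
anova_screen <- function(data, groups = "treatment", variables = NULL,
                         transforms = default_transforms()) {
  if (is.character(groups) && length(groups) == 1) {
    groups <- data[[groups]]
  }
  groups <- as.factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    abort("need >= 2 groups with >= 2 samples each.", class = "mfsoil_schema")
  }
  if (is.null(variables)) variables <- intersect(soil_variables(), names(data))
  data <- transform_variables(data, variables, transforms)
  posthoc <- list()
  out <- purrr::map(variables, function(v) {
    x <- data[[v]]
    fit <- aov(x ~ groups)
    tab <- summary(fit)[[1]]
    posthoc[[v]] <<- stats::pairwise.t.test(x, groups,
                                            p.adjust.method = "bonferroni")$p.value
    tibble(variable = v,
           F = tab[["F value"]][1],
           p = tab[["Pr(>F)"]][1],
           shapiro_p = shapiro.test(x)$p.value)
  }) |> bind_rows() |>
    mutate(significant = .data$p <= 0.05)
  attr(out, "posthoc") <- posthoc
  out
}
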