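#' Assemble the region x classifier dissociation table
#'
#' For every subject, the mean searchlight accuracy of each classifier
#' scheme inside each ROI.
#'
#' @param maps nested list: `maps[[scheme]][[subject]]` is an `AccuracyMap`.
#' @param rois named list of two 3D logical masks.
#' @return A `DissociationTable` data frame with columns subject, region,
#'   classifier, accuracy.
#' @export
dissociation_table <- function(maps, rois) {
  stopifnot(length(rois) == 2L, !is.null(names(rois)))
  rows <- list()
  for (sch in names(maps))
    for (s in seq_along(maps[[sch]]))
      for (rg in names(rois))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, region = rg, classifier = sch,
          accuracy = roi_mean_accuracy(maps[[sch]][[s]], rois[[rg]]))
  out <- do.call(rbind, rows)
  class(out) <- c("DissociationTable", "data.frame")
  out
}

#' Two-by-two repeated-measures dissociation ANOVA
#'
#' Within-subject ANOVA with factors region (2 levels) and classifier
#' (2 levels) on ROI prediction accuracies, each F on (1, n-1) degrees of
#' freedom, plus paired t-tests for the two simple effects of region within
#' each classifier.  With zero error variance an F is reported as NA with
#' an explanatory note.
#'
#' @param table data frame with columns subject, region, classifier,
#'   accuracy; the design must be complete (every subject crossed with both
#'   regions and both classifiers).
#' @return List with `anova` (data frame: effect, F, df1, df2, p) and
#'   `simple_effects` (data frame: classifier, t, df, p, mean_diff, with the
#'   difference taken between the first and second region level).
#' @export
dissociation_anova <- function(table) {
  tb <- as.data.frame(table)
  need <- c("subject", "region", "classifier", "accuracy")
  if (!all(need %in% names(tb)))
    stop("table must have columns ", paste(need, collapse = ", "))
  tb$subject <- factor(tb$subject)
  tb$region <- factor(tb$region)
  tb$classifier <- factor(tb$classifier)
  if (nlevels(tb$region) != 2L || nlevels(tb$classifier) != 2L)
    stop("region and classifier must each have exactly 2 levels")
  n <- nlevels(tb$subject)
  if (n < 3L) stop("need at least 3 subjects")
  counts <- table(tb$subject, tb$region, tb$classifier)
  if (any(counts != 1L)) {
    miss <- which(counts == 0L, arr.ind = TRUE)
    lab <- apply(miss, 1, function(i)
      sprintf("subject %s / region %s / classifier %s",
              levels(tb$subject)[i[1]], levels(tb$region)[i[2]],
              levels(tb$classifier)[i[3]]))
    stop("incomplete crossed design; missing cell(s): ",
         paste(lab, collapse = "; "))
  }
  if (any(!is.finite(tb$accuracy))) stop("accuracies must be finite")

  fit <- stats::aov(accuracy ~ region * classifier +
                      Error(subject / (region * classifier)), data = tb)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    st <- sm[[stratum]][[1]]
    i <- match(effect, trimws(rownames(st)))
    ss_eff <- st[i, "Sum Sq"]; df1 <- st[i, "Df"]
    j <- match("Residuals", trimws(rownames(st)))
    ss_err <- st[j, "Sum Sq"]; df2 <- st[j, "Df"]
    if (ss_err <= 1e-300) {
      return(data.frame(effect = effect, F = NA_real_, df1 = df1, df2 = df2,
                        p = NA_real_, note = "zero error variance"))
    }
    Fv <- (ss_eff / df1) / (ss_err / df2)
    data.frame(effect = effect, F = Fv, df1 = df1, df2 = df2,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE), note = "")
  }
  an <- rbind(pull("Error: subject:region", "region"),
              pull("Error: subject:classifier", "classifier"),
              pull("Error: subject:region:classifier", "region:classifier"))
  rownames(an) <- NULL

  rlev <- levels(tb$region)
  simple <- do.call(rbind, lapply(levels(tb$classifier), function(cl) {
    sl <- tb[tb$classifier == cl, ]
    wide <- stats::reshape(sl[, c("subject", "region", "accuracy")],
                           idvar = "subject", timevar = "region",
                           direction = "wide")
    d <- wide[[paste0("accuracy.", rlev[1])]] -
         wide[[paste0("accuracy.", rlev[2])]]
    if (stats::sd(d) == 0)
      return(data.frame(classifier = cl, t = NA_real_, df = n - 1,
                        p = NA_real_, mean_diff = mean(d)))
    tt <- stats::t.test(d)
    data.frame(classifier = cl, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, mean_diff = mean(d))
  }))
  list(anova = an, simple_effects = simple,
       region_levels = rlev, classifier_levels = levels(tb$classifier))
}
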