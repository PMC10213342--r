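# Published reference eigenvectors for the four-gene panel.

#' Published panel eigenvectors for the control and severe groups
#'
#' The previously reported eigenvector matrices of the uncentered Gram
#' matrix of the BAG2-HSC70-STUB1-MAPT panel in the GSE1297 hippocampus
#' cohort, for the control and severe severity groups. Columns are ordered
#' by descending eigenvalue (the first column belongs to the leading
#' eigenvalue); rows follow the published row order, whose exact
#' gene-to-row assignment is ambiguous in the source material, so
#' comparisons against these tables should be made on absolute component
#' values up to global column sign.
#'
#' The dot product of the two leading columns as printed is about -0.944:
#' the reported sign reversal of the panel's dominant direction between the
#' control and severe stages.
#'
#' @return named list of two 4 x 4 matrices, `control` and `severe`.
#' @export
reference_eigenvectors <- function() {
  control <- matrix(c(
     0.16039980, -0.86496189,  0.43869841,  0.18345718,
    -0.57748234,  0.26959268,  0.49608849,  0.58968648,
     0.50539008,  0.39466183,  0.71249652, -0.28490634,
     0.62077928,  0.15297958, -0.23192376,  0.73310415),
    nrow = 4, byrow = TRUE)
  severe <- matrix(c(
    -0.47158612,  0.43012550,  0.75178616,  0.16557825,
     0.47986946, -0.34906073,  0.61507755, -0.51919314,
    -0.49541599,  0.15885334, -0.21990490, -0.82520934,
    -0.54944958, -0.81726022,  0.09021649,  0.14849873),
    nrow = 4, byrow = TRUE)
  list(control = control, severe = severe)
}

#' Published leading eigenvalue fractions
#'
#' The reported leading eigenvalue fractions of the panel Gram spectrum:
#' 0.56 in the control group and 0.79 in the severe group.
#'
#' @return named numeric vector.
#' @export
reference_leading_fractions <- function() {
  c(control = 0.56, severe = 0.79)
}
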