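#' Canonical spermatogenic stage series
#'
#' The ordered developmental axis shared by every trajectory and timing
#' computation in the package: mitotic spermatogonia (Undiff, A1, B), meiotic
#' spermatocytes (pL, L, Z, mP, D), round spermatids (RS2, RS4, RS8),
#' elongating spermatids (LS) and mature sperm. All modules refer to this one
#' table rather than re-declaring an order.
#'
#' @return Character vector of stage identifiers, in developmental order.
#' @examples
#' spermatogenic_stages()
#' @export
spermatogenic_stages <- function() {
  c("Undiff", "A1", "B", "pL", "L", "Z", "mP", "D",
    "RS2", "RS4", "RS8", "LS", "Sperm")
}

#' Order stage labels along the canonical series
#'
#' @param x Character vector of stage identifiers.
#' @return Factor with levels in canonical developmental order.
#' @export
stage_factor <- function(x) {
  stages <- spermatogenic_stages()
  bad <- setdiff(unique(x), stages)
  if (length(bad) > 0L) {
    stop("unknown stage identifier(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = stages)
}

#' Sort a set of stage labels into developmental order
#'
#' @param x Character vector of stage identifiers (unique).
#' @return `x` reordered along the canonical series.
#' @export
order_stages <- function(x) {
  as.character(sort(stage_factor(x)))
}
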