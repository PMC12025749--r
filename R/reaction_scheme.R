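#' Construct a reversible catalytic cycle scheme
#'
#' A `reaction_scheme` describes an N-state (N in 2:4) reversible cyclic
#' enzyme mechanism: free enzyme E (state 1) binds substrate and cycles
#' counterclockwise through its intermediate conformations back to E,
#' releasing product. All transitions are treated as first-order processes:
#' the substrate- and product-binding steps carry the respective
#' concentration folded into the rate constant, so every element of `k` is
#' in s^-1. Odd positions k1, k3, ... are forward (counterclockwise)
#' constants, even positions k2, k4, ... are the corresponding reverse
#' constants; the binding step is k1 = k1_second_order * \[S\] and the
#' product-rebinding step is the last even constant
#' k\[2n\] = k_rev_bind_second_order * \[P\].
#'
#' Rate constants must be strictly positive: a genuinely irreversible step
#' (a zero reverse constant) makes the thermodynamic force infinite and the
#' dissipation undefined. Replace zeros by a small positive floor before
#' construction (see [read_schemes()], which does this with a configurable
#' floor).
#'
#' @param k numeric vector of 2*n_states positive first-order rate
#'   constants (s^-1), ordered k1, k2, ..., k\[2n\].
#' @param substrate_conc substrate concentration \[S\] in mol/L.
#' @param product_conc product concentration \[P\] in mol/L.
#' @param k1_second_order optional second-order substrate-binding constant
#'   (M^-1 s^-1); when given it must reproduce k\[1\]/\[S\] to 1e-9 relative.
#' @param k_rev_bind_second_order optional second-order product-binding
#'   constant (M^-1 s^-1); must reproduce k\[2n\]/\[P\] likewise.
#' @param label free-text identifier.
#' @return An object of class `reaction_scheme`.
#' @examples
#' sc <- reaction_scheme(c(2, 1, 1, 1), substrate_conc = 1e-3)
#' steady_state(sc)$flux  # 0.2
#' @export
reaction_scheme <- function(k, substrate_conc = NA_real_,
                            product_conc = NA_real_,
                            k1_second_order = NA_real_,
                            k_rev_bind_second_order = NA_real_,
                            label = "") {
  k <- as.numeric(k)
  if (length(k) %% 2L != 0L || !(length(k) / 2L) %in% 2:4) {
    stop("'k' must hold 2*n_states rate constants with n_states in {2, 3, 4}, got length ",
         length(k))
  }
  if (any(!is.finite(k))) stop("rate constants must be finite, got: ",
                               paste(k, collapse = ", "))
  if (any(k <= 0)) {
    stop("all rate constants must be strictly positive; replace zero reverse ",
         "constants by a small positive floor before construction ",
         "(offending positions: ", paste(which(k <= 0), collapse = ", "), ")")
  }
  n_states <- length(k) %/% 2L
  rel_ok <- function(a, b) abs(a - b) <= 1e-9 * max(abs(a), abs(b))
  if (!is.na(k1_second_order)) {
    if (is.na(substrate_conc) || substrate_conc <= 0)
      stop("a second-order binding constant requires a positive substrate_conc")
    if (!rel_ok(k1_second_order * substrate_conc, k[1]))
      stop("k1_second_order * [S] does not reproduce k1 (relative tolerance 1e-9)")
  }
  if (!is.na(k_rev_bind_second_order)) {
    if (is.na(product_conc) || product_conc <= 0)
      stop("a second-order product-binding constant requires a positive product_conc")
    if (!rel_ok(k_rev_bind_second_order * product_conc, k[2L * n_states]))
      stop("k_rev_bind_second_order * [P] does not reproduce the last reverse ",
           "constant (relative tolerance 1e-9)")
  }
  structure(
    list(n_states = n_states, k = k,
         substrate_conc = as.numeric(substrate_conc),
         product_conc = as.numeric(product_conc),
         k1_second_order = as.numeric(k1_second_order),
         k_rev_bind_second_order = as.numeric(k_rev_bind_second_order),
         label = as.character(label)),
    class = "reaction_scheme")
}

#' @export
print.reaction_scheme <- function(x, ...) {
  cat(sprintf("<reaction_scheme> %s-state cycle%s\n", x$n_states,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  cat("  forward k (s^-1):", format(x$k[seq(1, length(x$k), 2)], digits = 4), "\n")
  cat("  reverse k (s^-1):", format(x$k[seq(2, length(x$k), 2)], digits = 4), "\n")
  if (!is.na(x$substrate_conc))
    cat(sprintf("  [S] = %g M, [P] = %g M\n", x$substrate_conc, x$product_conc))
  invisible(x)
}

fwd_k <- function(scheme) scheme$k[seq(1L, 2L * scheme$n_states, 2L)]
rev_k <- function(scheme) scheme$k[seq(2L, 2L * scheme$n_states, 2L)]

stop_unless_scheme <- function(scheme) {
  if (!inherits(scheme, "reaction_scheme"))
    stop("expected a 'reaction_scheme' object")
  invisible(scheme)
}

#' Read catalytic cycle schemes from a rate-constant table
#'
#' Reads a CSV/TSV file with one scheme per row and the header
#' `label, n_states, k1..k8, S_molar, P_molar` plus optional
#' `k1_second_order, k_rev_bind_second_order` columns. Trailing k-columns
#' beyond 2*n_states must be empty. Zero reverse rate constants (reported
#' for effectively irreversible steps) are replaced by `zero_floor` with a
#' message, since a zero reverse constant implies an infinite force.
#'
#' @param path file path.
#' @param zero_floor positive substitute (s^-1) for reverse constants
#'   reported as zero. Default 1e-8 s^-1, the value conventionally used for
#'   the practically irreversible chorismate-mutase step.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return list of [reaction_scheme()] objects.
#' @seealso [write_schemes()]
#' @export
read_schemes <- function(path, zero_floor = 1e-8, sep = ",") {
  stopifnot(is.numeric(zero_floor), zero_floor > 0)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("label", "n_states", paste0("k", 1:8), "S_molar", "P_molar")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("scheme table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    n <- as.integer(row$n_states)
    if (!n %in% 2:4)
      stop("row ", i, " ('", row$label, "'): unsupported n_states = ", n)
    k <- as.numeric(row[paste0("k", seq_len(2L * n))])
    trailing <- unlist(row[paste0("k", setdiff(1:8, seq_len(2L * n)))])
    if (any(!is.na(suppressWarnings(as.numeric(trailing)))))
      stop("row ", i, " ('", row$label, "'): trailing k columns must be empty")
    if (any(is.na(k)))
      stop("row ", i, " ('", row$label, "'): missing rate constants")
    zero_rev <- which(k == 0)
    if (length(zero_rev)) {
      message("row ", i, " ('", row$label, "'): substituting floor ",
              zero_floor, " s^-1 for zero rate constant(s) at position(s) ",
              paste(zero_rev, collapse = ", "))
      k[zero_rev] <- zero_floor
    }
    so1 <- if ("k1_second_order" %in% names(df))
      as.numeric(row$k1_second_order) else NA_real_
    so2 <- if ("k_rev_bind_second_order" %in% names(df))
      as.numeric(row$k_rev_bind_second_order) else NA_real_
    reaction_scheme(k, substrate_conc = as.numeric(row$S_molar),
                    product_conc = as.numeric(row$P_molar),
                    k1_second_order = so1, k_rev_bind_second_order = so2,
                    label = as.character(row$label))
  })
}

#' Write catalytic cycle schemes to a rate-constant table
#'
#' Inverse of [read_schemes()]: one row per scheme, unused trailing
#' k-columns left empty.
#'
#' @param schemes list of [reaction_scheme()] objects.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_schemes <- function(schemes, path, sep = ",") {
  rows <- lapply(schemes, function(sc) {
    stop_unless_scheme(sc)
    k <- rep(NA_real_, 8)
    k[seq_along(sc$k)] <- sc$k
    data.frame(label = sc$label, n_states = sc$n_states,
               k1 = k[1], k2 = k[2], k3 = k[3], k4 = k[4],
               k5 = k[5], k6 = k[6], k7 = k[7], k8 = k[8],
               S_molar = sc$substrate_conc, P_molar = sc$product_conc,
               k1_second_order = sc$k1_second_order,
               k_rev_bind_second_order = sc$k_rev_bind_second_order,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Run code under a private RNG stream without disturbing the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
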