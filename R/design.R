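#' Component specification
#'
#' A named cognitive component of a matrix-test design: either an abstract
#' rule (e.g. the Carpenter rules CR, PP, A/S, D3, D2) or a figural drawing
#' property (overlay, distortion, fusion).
#'
#' @param name Component name, unique within a design.
#' @param kind `"rule"` or `"figural"`.
#' @return A one-row data frame with columns `name` and `kind`.
#' @export
component_spec <- function(name, kind = c("rule", "figural")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  data.frame(name = name, kind = kind, stringsAsFactors = FALSE)
}

#' Default ART-like component set
#'
#' The five Carpenter rules plus the three figural properties used by
#' Abstract-Reasoning-Test-style progressive matrices.
#'
#' @return An 8-row component data frame.
#' @export
art_components <- function() {
  rbind(
    component_spec("CR", "rule"),
    component_spec("PP", "rule"),
    component_spec("A/S", "rule"),
    component_spec("D3", "rule"),
    component_spec("D2", "rule"),
    component_spec("overlay", "figural"),
    component_spec("distortion", "figural"),
    component_spec("fusion", "figural")
  )
}

#' Construct a test design
#'
#' A test design couples a J x M structure matrix `W` of nonnegative
#' component weights (w\[j,m\] = number of applications of component m in
#' item j) with the component definitions. Item order is administration
#' order, which is what gives the cumulative-practice matrix its meaning.
#'
#' @param W Numeric J x M matrix of nonnegative weights; columns are matched
#'   to `components` by position (and named after them).
#' @param components Data frame with columns `name`, `kind` (see
#'   [component_spec()]); defaults to [art_components()] when `W` has 8
#'   columns.
#' @return An object of class `oslm_design` with elements `W`, `components`,
#'   `J`, `M`.
#' @export
test_design <- function(W, components = NULL) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  if (is.null(components)) {
    if (ncol(W) == 8L) components <- art_components()
    else stop("`components` must be supplied when W does not have 8 columns")
  }
  if (nrow(components) != ncol(W))
    stop("number of components (", nrow(components),
         ") does not match ncol(W) (", ncol(W), ")")
  if (anyDuplicated(components$name))
    stop("component names must be unique")
  if (!all(components$kind %in% c("rule", "figural")))
    stop("component kind must be 'rule' or 'figural'")
  if (nrow(W) < 1L) stop("design needs at least one item")
  if (anyNA(W) || any(!is.finite(W))) stop("W contains non-finite weights")
  if (any(W < 0)) stop("W contains negative weights")
  if (any(colSums(W) == 0))
    stop("every component must appear in at least one item; all-zero column: ",
         paste(components$name[colSums(W) == 0], collapse = ", "))
  if (any(W != round(W)))
    warning("W contains non-integer weights; LLTM-family weights are usually counts")
  colnames(W) <- components$name
  rownames(W) <- NULL
  structure(list(W = W, components = components,
                 J = nrow(W), M = ncol(W)),
            class = "oslm_design")
}

#' @export
print.oslm_design <- function(x, ...) {
  cat("Test design:", x$J, "items x", x$M, "components\n")
  cat("  rules:   ", paste(x$components$name[x$components$kind == "rule"],
                           collapse = ", "), "\n")
  cat("  figural: ", paste(x$components$name[x$components$kind == "figural"],
                           collapse = ", "), "\n")
  invisible(x)
}

#' Cumulative-practice matrix
#'
#' Derives the practice matrix `V` from the structure matrix: the practice
#' weight of component m at item j is the item's own weight times the total
#' weight of m over all earlier items,
#' `v[j,m] = w[j,m] * sum(W[1:(j-1), m])`. A component therefore carries no
#' practice weight at its first appearance, and row 1 of `V` is all zeros.
#' `V_plus` is `V` augmented with a column of ones (used by the
#' identification check).
#'
#' @param design An [test_design()] object.
#' @return An object of class `oslm_practice` with elements `V`, `V_plus`.
#' @export
build_practice_matrix <- function(design) {
  stopifnot(inherits(design, "oslm_design"))
  W <- design$W
  csum <- apply(W, 2, cumsum)
  if (design$J == 1L) csum <- matrix(csum, nrow = 1L)
  prior <- rbind(0, csum[-design$J, , drop = FALSE])
  V <- W * prior
  dimnames(V) <- dimnames(W)
  V_plus <- cbind(V, `(practice intercept)` = 1)
  structure(list(V = V, V_plus = V_plus), class = "oslm_practice")
}

num_rank <- function(A) {
  if (length(A) == 0L) return(0L)
  s <- svd(A, nu = 0, nv = 0)$d
  tol <- max(dim(A)) * .Machine$double.eps * max(s)
  sum(s > tol)
}

#' Check model identification
#'
#' For the practice models the structure matrix `W`, the augmented practice
#' matrix `V+ = (V, 1)` and their concatenation `[W | V+]` must all have full
#' column rank, and the number of component effects must not exceed the
#' number of items (`2M + 1 <= J`). For the practice-free LLTM/RWLLTM only
#' the rank of `W` and `M <= J` are relevant. Numerical rank uses the
#' singular-value threshold `max(dim) * eps * sigma_max`.
#'
#' @param design An [test_design()] object.
#' @param practice Matching [build_practice_matrix()] output (ignored for
#'   practice-free variants; may be `NULL` then).
#' @param spec A [model_spec()]; defaults to the full RWOSLM so that all
#'   conditions are checked.
#' @return An `oslm_identification` report with logical flags `rank_W_ok`,
#'   `rank_Vplus_ok`, `rank_concat_ok`, `effect_count_ok`, an overall `pass`,
#'   and human-readable `messages`.
#' @export
check_identification <- function(design, practice = NULL,
                                 spec = model_spec("RWOSLM")) {
  stopifnot(inherits(design, "oslm_design"))
  W <- design$W
  J <- design$J; M <- design$M
  practice_free <- all(spec$practice_mode == "none")
  if (!practice_free) {
    if (is.null(practice)) practice <- build_practice_matrix(design)
    stopifnot(inherits(practice, "oslm_practice"))
    if (!identical(dim(practice$V), dim(W)))
      stop("practice matrix shape does not match design")
  }
  msgs <- character()
  rank_W_ok <- num_rank(W) == M
  if (!rank_W_ok) msgs <- c(msgs, "W is column-rank deficient")
  if (practice_free) {
    rank_Vplus_ok <- TRUE
    rank_concat_ok <- TRUE
    effect_count_ok <- M <= J
    if (!effect_count_ok)
      msgs <- c(msgs, sprintf("more component effects than items (M = %d > J = %d)", M, J))
  } else {
    Vp <- practice$V_plus
    rank_Vplus_ok <- num_rank(Vp) == ncol(Vp)
    if (!rank_Vplus_ok) msgs <- c(msgs, "V+ = (V, 1) is column-rank deficient")
    rank_concat_ok <- num_rank(cbind(W, Vp)) == (M + ncol(Vp))
    if (!rank_concat_ok) msgs <- c(msgs, "[W | V+] is column-rank deficient")
    effect_count_ok <- (2 * M + 1) <= J
    if (!effect_count_ok)
      msgs <- c(msgs, sprintf("too many effects: 2M + 1 = %d > J = %d", 2 * M + 1, J))
  }
  pass <- rank_W_ok && rank_Vplus_ok && rank_concat_ok && effect_count_ok
  if (pass) msgs <- c(msgs, "all identification conditions satisfied")
  structure(list(rank_W_ok = rank_W_ok, rank_Vplus_ok = rank_Vplus_ok,
                 rank_concat_ok = rank_concat_ok,
                 effect_count_ok = effect_count_ok,
                 pass = pass, messages = msgs),
            class = "oslm_identification")
}

#' @export
print.oslm_identification <- function(x, ...) {
  cat("Identification:", if (x$pass) "PASS" else "FAIL", "\n")
  for (m in x$messages) cat("  -", m, "\n")
  invisible(x)
}

#' Read / write a test design
#'
#' CSV layout: header `item,<component names...>`, one row per item in
#' administration order (component kinds are inferred: names among the ART
#' figural properties are `figural`, others `rule`; use JSON to state kinds
#' explicitly). JSON layout:
#' `{"components": [{"name": ..., "kind": ...}, ...], "W": [[...], ...]}`.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the file extension by
#'   default.
#' @return `read_design()` returns an [test_design()]; `write_design()`
#'   returns `path` invisibly. Round trip is exact.
#' @export
read_design <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE)
    if (!"item" %in% names(df)) stop("design CSV must have an 'item' column")
    W <- as.matrix(df[, setdiff(names(df), "item"), drop = FALSE])
    if (!is.numeric(W)) stop("design CSV contains non-numeric weights")
    fig <- c("overlay", "distortion", "fusion")
    comps <- data.frame(name = colnames(W),
                        kind = ifelse(colnames(W) %in% fig, "figural", "rule"),
                        stringsAsFactors = FALSE)
    test_design(W, comps)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(obj$components)) stop("design JSON missing field 'components'")
    comps <- obj$components
    if (!is.data.frame(comps)) comps <- as.data.frame(comps,
                                                      stringsAsFactors = FALSE)
    if (is.null(comps$name)) stop("design JSON missing component field 'name'")
    if (is.null(comps$kind)) stop("design JSON missing component field 'kind'")
    if (is.null(obj$W)) stop("design JSON missing field 'W'")
    test_design(obj$W, comps[, c("name", "kind")])
  }
}

#' @rdname read_design
#' @param design An [test_design()] object.
#' @export
write_design <- function(design, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(design, "oslm_design"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- data.frame(item = seq_len(design$J), check.names = FALSE)
    df <- cbind(df, as.data.frame(design$W, check.names = FALSE))
    write.csv(df, path, row.names = FALSE, quote = TRUE)
  } else {
    obj <- list(components = design$components,
                W = unname(design$W))
    jsonlite::write_json(obj, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}
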