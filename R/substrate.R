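#' RNA substrates with 3'-anchored tail indexing
#'
#' A tail substrate is a short RNA "body" followed by a poly(A)-type tail of
#' length `N`. Tail positions are counted from the 3' terminus: position
#' `p = 1` is the 3'-most residue of the intact tail and `p = N` abuts the
#' body. This is the coordinate in which per-position removal rates and
#' stalling statistics are reported, and it maps one-to-one onto gel species:
#' the removal event taking species `s` to `s + 1` hydrolyses the residue at
#' tail position `p = s` (species 1 is the intact substrate, species `N + 1`
#' the tailless body).
#'
#' @param name Substrate label, e.g. `"A20G"`.
#' @param body Body sequence 5'->3' (RNA alphabet `A`, `G`, `U`, `C`).
#' @param tail Tail sequence 5'->3', same alphabet, length >= 1.
#'
#' @return An object of class `tail_substrate`.
#' @examples
#' sub <- tail_substrate("A4G", "UCUACAU", "AGAA")
#' residue(sub, 1)           # 3'-most residue
#' non_a_positions(sub)      # tail positions from the 3' end
#' @export
tail_substrate <- function(name, body, tail) {
  body <- toupper(gsub("T", "U", body))
  tail <- toupper(gsub("T", "U", tail))
  check_rna <- function(x, what) {
    chars <- strsplit(x, "")[[1]]
    if (length(chars) == 0 || !all(chars %in% c("A", "G", "U", "C"))) {
      abort(sprintf("`%s` must be a non-empty string over {A, G, U, C}.", what))
    }
  }
  check_rna(body, "body")
  check_rna(tail, "tail")
  structure(
    list(name = as.character(name), body = body, tail = tail),
    class = "tail_substrate"
  )
}

#' @export
print.tail_substrate <- function(x, ...) {
  cat(sprintf(
    "<tail_substrate> %s: 5'-%s + %s-3' (tail %d nt",
    x$name, x$body, x$tail, tail_length(x)
  ))
  nonA <- non_a_positions(x)
  if (length(nonA)) {
    cat(sprintf(
      ", non-A at 3'-position%s %s",
      if (length(nonA) > 1) "s" else "", paste(nonA, collapse = ", ")
    ))
  }
  cat(")\n")
  invisible(x)
}

#' @rdname tail_substrate
#' @param substrate A `tail_substrate`.
#' @export
tail_length <- function(substrate) {
  stopifnot(inherits(substrate, "tail_substrate"))
  nchar(substrate$tail)
}

#' @rdname tail_substrate
#' @param p Tail position(s), counted from the 3' end (`p = 1` is 3'-most).
#' @export
residue <- function(substrate, p) {
  stopifnot(inherits(substrate, "tail_substrate"))
  N <- tail_length(substrate)
  if (any(p < 1 | p > N)) abort("Tail position out of range.")
  chars <- strsplit(substrate$tail, "")[[1]]
  chars[N - p + 1]
}

#' @rdname tail_substrate
#' @export
non_a_positions <- function(substrate) {
  N <- tail_length(substrate)
  p <- seq_len(N)
  p[residue(substrate, p) != "A"]
}

#' Built-in substrate presets
#'
#' The assay designs used throughout: a 7-mer body (`UCUACAU`) carrying a
#' 20-nt tail that is either pure poly(A) (`A20`) or has two intermittent
#' non-adenosine residues at tail positions 7 and 14 from the 3' end
#' (`A20G`, `A20U`, `A20C`), plus a longer pure-A control (`A60`).
#'
#' @param name One of `"A20"`, `"A20G"`, `"A20U"`, `"A20C"`, `"A60"`.
#' @return A [tail_substrate()].
#' @examples
#' substrate_preset("A20G")
#' @export
substrate_preset <- function(name = c("A20", "A20G", "A20U", "A20C", "A60")) {
  name <- match.arg(name)
  body <- "UCUACAU"
  mixed_tail <- function(base) {
    chars <- rep("A", 20)
    # tail string is 5'->3'; 3'-anchored positions 7 and 14 are string
    # indices 20 - p + 1
    chars[20 - c(7, 14) + 1] <- base
    paste(chars, collapse = "")
  }
  tail <- switch(name,
    A20  = strrep("A", 20),
    A60  = strrep("A", 60),
    A20G = mixed_tail("G"),
    A20U = mixed_tail("U"),
    A20C = mixed_tail("C")
  )
  tail_substrate(name, body, tail)
}

#' Read substrates from FASTA or YAML
#'
#' FASTA records hold the full sequence 5'->3' (body then tail); the tail
#' boundary is supplied as `tail_length` (one value, recycled, or one per
#' record). YAML files hold a list of records with `name`, `body` and `tail`
#' fields.
#'
#' @param path File path.
#' @param tail_length Tail length(s) in nucleotides for FASTA input.
#' @return A list of [tail_substrate()] objects (length one is unwrapped).
#' @export
read_substrate_fasta <- function(path, tail_length) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Reading FASTA substrates requires the Biostrings package.")
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort("No FASTA records found.")
  tail_length <- rep_len(as.integer(tail_length), length(seqs))
  subs <- map2(as.character(seqs), tail_length, function(s, tl) {
    n <- nchar(s)
    if (tl < 1 || tl >= n) abort("`tail_length` must be in [1, nchar - 1].")
    tail_substrate(
      name = NA_character_,
      body = substr(s, 1, n - tl),
      tail = substr(s, n - tl + 1, n)
    )
  })
  for (i in seq_along(subs)) subs[[i]]$name <- names(seqs)[i]
  if (length(subs) == 1) subs[[1]] else subs
}

#' @rdname read_substrate_fasta
#' @export
read_substrate_yaml <- function(path) {
  recs <- yaml::read_yaml(path)
  if (length(recs) == 0) abort("No substrate records found.")
  subs <- map(recs, function(r) {
    if (is.null(r$name) || is.null(r$body) || is.null(r$tail)) {
      abort("Each YAML substrate record needs `name`, `body` and `tail`.")
    }
    tail_substrate(r$name, r$body, r$tail)
  })
  if (length(subs) == 1) subs[[1]] else subs
}
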