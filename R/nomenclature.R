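# Protein-level HGVS parsing and canonicalization.
#
# Laboratories render the same protein change in many dialects
# (p.(Val600Arg), p(Val600Arg), p.Val600Arg, p.V600R, p.Val600delinsArg,
# p.V600delinsR, ...). Everything downstream matches variants on the
# canonical form produced here, falling back to genomic coordinates when a
# string cannot be parsed.

.AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Ter = "*"
)
.AA1_TO_3 <- stats::setNames(names(.AA3_TO_1), unname(.AA3_TO_1))

#' Amino-acid code tables
#'
#' Lossless maps between one- and three-letter amino-acid codes for the 20
#' standard residues plus the stop codon (`Ter`/`*`).
#'
#' @return A named character vector; `aa_three_to_one()` maps three-letter
#'   codes to one-letter codes, `aa_one_to_three()` the inverse.
#' @export
aa_three_to_one <- function() .AA3_TO_1

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function() .AA1_TO_3

# Take one residue code from the head of `s`. Three-letter codes (incl. Ter)
# are tried first, then one-letter codes (incl. "*"). Returns list(aa, rest)
# with aa in three-letter form, or NULL.
take_residue <- function(s) {
  m <- regmatches(s, regexec("^([A-Z][a-z]{2})", s))[[1]]
  if (length(m) && m[2] %in% names(.AA3_TO_1)) {
    return(list(aa = m[2], rest = substring(s, 4L)))
  }
  c1 <- substring(s, 1L, 1L)
  if (c1 %in% names(.AA1_TO_3)) {
    return(list(aa = unname(.AA1_TO_3[c1]), rest = substring(s, 2L)))
  }
  NULL
}

# Residue code followed by a 1-based position, e.g. "Val600" or "V600".
take_residue_pos <- function(s) {
  r <- take_residue(s)
  if (is.null(r)) return(NULL)
  m <- regmatches(r$rest, regexec("^([0-9]+)", r$rest))[[1]]
  if (!length(m)) return(NULL)
  list(aa = r$aa, pos = as.integer(m[2]), rest = substring(r$rest, nchar(m[2]) + 1L))
}

# Parse a full residue sequence such as "IlePro" or "IP" into three-letter
# codes. The whole string must be consistently three- or one-letter.
parse_residue_seq <- function(s) {
  if (!nzchar(s)) return(NULL)
  if (nchar(s) %% 3L == 0L) {
    chunks <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    if (all(chunks %in% names(.AA3_TO_1))) return(chunks)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (all(chars %in% names(.AA1_TO_3))) return(unname(.AA1_TO_3[chars]))
  NULL
}

new_protein_change <- function(kind, ref_aa, pos, alt = character(),
                               fs_new = NA_character_, fs_offset = NA_integer_) {
  structure(
    list(kind = kind, ref_aa = ref_aa, pos = pos, alt = alt,
         fs_new = fs_new, fs_offset = fs_offset),
    class = "protein_change"
  )
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change> ", x$kind, ": ", canonicalize_protein(x), "\n", sep = "")
  invisible(x)
}

#' Parse a protein-level HGVS string tolerantly
#'
#' Accepts the dialect space observed in practice: optional `p.`/`p` prefix,
#' optional parentheses, one- or three-letter amino-acid codes, `*`/`Ter` for
#' the stop codon, ranges separated by `_` or `-`, and the `del`, `dup`,
#' `ins`, `delins` and frameshift (`fs`, `fs*N`, `fsTerN`) forms.
#'
#' @param text A single protein HGVS string, e.g. `"p.V600R"`.
#' @return A `protein_change` object, or `NULL` when the string cannot be
#'   parsed (the caller is expected to fall back to genomic coordinates).
#' @examples
#' parse_protein_hgvs("p.V600R")
#' parse_protein_hgvs("p.(Glu746_Ala750delinsIlePro)")
#' @export
parse_protein_hgvs <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) return(NULL)
  s <- gsub("[[:space:]]+", "", text)
  s <- sub("^p\\.?", "", s)
  if (startsWith(s, "(") && endsWith(s, ")")) s <- substring(s, 2L, nchar(s) - 1L)
  if (grepl("[()]", s)) return(NULL)

  first <- take_residue_pos(s)
  if (is.null(first)) return(NULL)
  ref_aa <- first$aa
  pos <- first$pos
  rest <- first$rest

  # optional range: "_" per HGVS, "-" tolerated (seen in the wild)
  if (grepl("^[_-]", rest)) {
    second <- take_residue_pos(substring(rest, 2L))
    if (is.null(second)) return(NULL)
    if (second$pos <= pos) return(NULL)
    ref_aa <- c(ref_aa, second$aa)
    pos <- c(pos, second$pos)
    rest <- second$rest
  }
  ranged <- length(pos) > 1L

  if (startsWith(rest, "delins")) {
    alt <- parse_residue_seq(substring(rest, 7L))
    if (is.null(alt)) return(NULL)
    return(canonical_reduce(new_protein_change("delins", ref_aa, pos, alt)))
  }
  if (rest == "del") {
    return(new_protein_change("deletion", ref_aa, pos))
  }
  if (rest == "dup") {
    return(new_protein_change("duplication", ref_aa, pos))
  }
  if (startsWith(rest, "ins")) {
    if (!ranged) return(NULL)
    alt <- parse_residue_seq(substring(rest, 4L))
    if (is.null(alt)) return(NULL)
    return(new_protein_change("insertion", ref_aa, pos, alt))
  }
  if (ranged) return(NULL)

  if (grepl("^fs", rest)) {
    off <- parse_fs_offset(rest)
    if (is.null(off)) return(NULL)
    return(new_protein_change("frameshift", ref_aa, pos, fs_offset = off))
  }

  altr <- take_residue(rest)
  if (is.null(altr)) return(NULL)
  if (!nzchar(altr$rest)) {
    kind <- if (altr$aa == "Ter") "nonsense" else "substitution"
    return(new_protein_change(kind, ref_aa, pos, altr$aa))
  }
  if (grepl("^fs", altr$rest)) {
    off <- parse_fs_offset(altr$rest)
    if (is.null(off)) return(NULL)
    if (altr$aa == "Ter") return(NULL)
    return(new_protein_change("frameshift", ref_aa, pos,
                              fs_new = altr$aa, fs_offset = off))
  }
  NULL
}

# "fs", "fs*7", "fsTer7" -> integer offset (NA when unknown); NULL on junk.
parse_fs_offset <- function(s) {
  if (s == "fs") return(NA_integer_)
  m <- regmatches(s, regexec("^fs(\\*|Ter)([0-9]+)$", s))[[1]]
  if (!length(m)) return(NULL)
  off <- as.integer(m[3])
  if (off < 1L) return(NULL)
  off
}

# A delins touching a single residue and producing a single residue is the
# same event as a substitution (p.Val600delinsArg == p.(Val600Arg)).
canonical_reduce <- function(ch) {
  if (ch$kind == "delins" && length(ch$pos) == 1L && length(ch$alt) == 1L) {
    kind <- if (ch$alt == "Ter") "nonsense" else "substitution"
    return(new_protein_change(kind, ch$ref_aa, ch$pos, ch$alt))
  }
  ch
}

render_aa <- function(aa) ifelse(aa == "Ter", "*", aa)

#' Canonical protein HGVS rendering
#'
#' Deterministically renders a `protein_change` as `p.(...)` in three-letter
#' code with parentheses, `*` for the stop codon and `_` as range separator.
#' Single-residue delins events are reduced to substitutions.
#'
#' @param change A `protein_change` from [parse_protein_hgvs()].
#' @return A canonical HGVS protein string.
#' @examples
#' canonicalize_protein(parse_protein_hgvs("p.Val600delinsArg"))
#' @export
canonicalize_protein <- function(change) {
  stopifnot(inherits(change, "protein_change"))
  ch <- canonical_reduce(change)
  anchor <- paste0(ch$ref_aa[1], ch$pos[1])
  range <- if (length(ch$pos) > 1L) {
    paste0(anchor, "_", ch$ref_aa[2], ch$pos[2])
  } else {
    anchor
  }
  body <- switch(
    ch$kind,
    substitution = paste0(anchor, render_aa(ch$alt)),
    nonsense = paste0(anchor, "*"),
    deletion = paste0(range, "del"),
    duplication = paste0(range, "dup"),
    insertion = paste0(range, "ins", paste(render_aa(ch$alt), collapse = "")),
    delins = paste0(range, "delins", paste(render_aa(ch$alt), collapse = "")),
    frameshift = paste0(
      anchor,
      if (!is.na(ch$fs_new)) ch$fs_new else "",
      "fs",
      if (!is.na(ch$fs_offset)) paste0("*", ch$fs_offset) else ""
    ),
    stop("unknown protein change kind: ", ch$kind)
  )
  paste0("p.(", body, ")")
}

#' Canonicalize a protein HGVS string
#'
#' Convenience composition of [parse_protein_hgvs()] and
#' [canonicalize_protein()].
#'
#' @param text A protein HGVS string.
#' @return The canonical string, or `NA_character_` when unparseable.
#' @export
canonical_p_hgvs <- function(text) {
  vapply(text, function(t) {
    ch <- parse_protein_hgvs(t)
    if (is.null(ch)) NA_character_ else canonicalize_protein(ch)
  }, character(1), USE.NAMES = FALSE)
}

#' Build a matching key for a variant
#'
#' The key is `GENE|<canonical protein HGVS>` when the protein description
#' parses, and `GENE|g|chrom:pos` otherwise (protein-first matching with a
#' genomic fallback; the two levels are never mixed).
#'
#' @param gene Gene symbol.
#' @param p_hgvs Protein HGVS string as submitted (may be `NA`).
#' @param chrom,pos Genomic coordinate (1-based) used for the fallback.
#' @return A character vector of keys; `NA` when neither level is available.
#' @export
variant_key <- function(gene, p_hgvs, chrom = NA_character_, pos = NA_integer_) {
  n <- max(length(gene), length(p_hgvs), length(chrom), length(pos))
  gene <- rep_len(toupper(as.character(gene)), n)
  p_hgvs <- rep_len(as.character(p_hgvs), n)
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  canon <- canonical_p_hgvs(p_hgvs)
  out <- ifelse(!is.na(canon), paste0(gene, "|", canon),
                ifelse(!is.na(chrom) & !is.na(pos),
                       paste0(gene, "|g|", chrom, ":", pos),
                       NA_character_))
  out
}

#' Are two reported variants the same variant?
#'
#' Gene symbols must match (case-insensitively). When both protein
#' descriptions parse, equality is decided on the canonical protein form
#' (so a range deletion and a delins with a different outcome are distinct,
#' and frameshifts with different `fs*N` offsets are distinct). When either
#' side fails to parse, the comparison falls back to genomic coordinates
#' (chrom and 1-based position, plus ref/obs nucleotides when both sides
#' carry them).
#'
#' @param a,b Lists (or one-row data frames) with elements `gene`, `p_hgvs`
#'   and optionally `chrom`, `pos`, `ref_nt`, `obs_nt`.
#' @return `TRUE` or `FALSE`.
#' @export
variants_equivalent <- function(a, b) {
  ga <- toupper(as.character(a$gene))
  gb <- toupper(as.character(b$gene))
  if (is.na(ga) || is.na(gb) || ga != gb) return(FALSE)
  pa <- parse_protein_hgvs(one_or_na(a$p_hgvs))
  pb <- parse_protein_hgvs(one_or_na(b$p_hgvs))
  if (!is.null(pa) && !is.null(pb)) {
    return(canonicalize_protein(pa) == canonicalize_protein(pb))
  }
  ca <- one_or_na(a$chrom); cb <- one_or_na(b$chrom)
  qa <- one_or_na(a$pos); qb <- one_or_na(b$pos)
  if (is.na(ca) || is.na(cb) || is.na(qa) || is.na(qb)) return(FALSE)
  if (as.character(ca) != as.character(cb) || qa != qb) return(FALSE)
  ra <- one_or_na(a$ref_nt); rb <- one_or_na(b$ref_nt)
  oa <- one_or_na(a$obs_nt); ob <- one_or_na(b$obs_nt)
  if (!is.na(ra) && !is.na(rb) && ra != rb) return(FALSE)
  if (!is.na(oa) && !is.na(ob) && oa != ob) return(FALSE)
  TRUE
}

one_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NA)
  x[[1]]
}
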