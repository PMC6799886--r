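# Phenome construction: (i) phecode case/control sets with hierarchical
# rollup and exclusion-range control pools; (ii) the ICD-10 classification
# tree with per-node case indicators for the Bayesian tree scan.

#' Dotted ancestors of a phecode
#'
#' `"274.11"` has ancestors `"274.1"` and `"274"`: each assigned phecode also
#' assigns every less-specific code above it (hierarchy rollup).
#'
#' @param phecode Character scalar.
#' @return Character vector of ancestors, nearest first (empty for integer
#'   phecodes).
#' @export
phecode_ancestors <- function(phecode) {
  out <- character()
  p <- phecode
  while (grepl(".", p, fixed = TRUE)) {
    p <- sub("\\.?[0-9]$", "", p)
    out <- c(out, p)
  }
  out
}

#' Map diagnosis records to phecode assignments
#'
#' Longest-prefix match of each normalized ICD code against the map entries
#' of the same code system (`I21.0` matches a map entry for `I21` when no
#' more specific entry exists). Each assigned phecode also assigns all its
#' dotted ancestors. Unmapped codes are counted, not fatal.
#'
#' @param diagnoses A `diagnosis_records` data frame.
#' @param map A `phecode_map` data frame.
#' @return Data frame `person_id`, `phecode` (unique pairs), with attributes
#'   `n_unmapped_codes` (distinct unmappable codes) and `unmapped_codes`.
#' @export
map_to_phecodes <- function(diagnoses, map) {
  key <- unique(data.frame(person_id = diagnoses$person_id,
                           system = diagnoses$system, code = diagnoses$code))
  ucodes <- unique(key[c("system", "code")])
  lookup <- character(nrow(ucodes))
  for (i in seq_len(nrow(ucodes))) {
    cand <- map[map$system == ucodes$system[i] &
                startsWith(ucodes$code[i], map$icd), , drop = FALSE]
    lookup[i] <- if (nrow(cand)) cand$phecode[which.max(nchar(cand$icd))] else NA_character_
  }
  unmapped <- ucodes[is.na(lookup), , drop = FALSE]
  if (nrow(unmapped)) {
    warn_pwmr("map_to_phecodes: %d distinct code(s) unmapped", nrow(unmapped))
  }
  ck <- paste(ucodes$system, ucodes$code)
  assigned <- lookup[match(paste(key$system, key$code), ck)]
  keep <- !is.na(assigned)
  base <- data.frame(person_id = key$person_id[keep], phecode = assigned[keep])
  rolled <- lapply(unique(base$phecode), function(p) {
    anc <- phecode_ancestors(p)
    if (!length(anc)) return(NULL)
    persons <- base$person_id[base$phecode == p]
    data.frame(person_id = rep(persons, times = length(anc)),
               phecode = rep(anc, each = length(persons)))
  })
  out <- unique(rbind(base, do.call(rbind, rolled)))
  rownames(out) <- NULL
  attr(out, "n_unmapped_codes") <- nrow(unmapped)
  attr(out, "unmapped_codes") <- paste(unmapped$system, unmapped$code)
  out
}

phecode_exclusion_range <- function(phecode, map) {
  rows <- map[map$phecode == phecode & nzchar(map$exclude_low), , drop = FALSE]
  if (!nrow(rows)) {
    # Rolled-up ancestor without its own map row: exclusion is the union of
    # its descendants' ranges.
    desc <- map[startsWith(map$phecode, paste0(phecode, ".")) &
                nzchar(map$exclude_low), , drop = FALSE]
    rows <- desc
  }
  if (!nrow(rows)) return(NULL)
  c(min(as.numeric(rows$exclude_low)), max(as.numeric(rows$exclude_high)))
}

#' Assemble the case/control set for one phecode
#'
#' Cases are the persons assigned the phecode. Controls are all other
#' persons with no assignment inside the phecode's exclusion range, so
#' similar or potentially overlapping disease states never contaminate the
#' control pool. Sets with fewer than `min_cases` cases are marked filtered.
#'
#' @param phecode Target phecode.
#' @param assignments Assignment table from [map_to_phecodes()].
#' @param map A `phecode_map`.
#' @param persons Character vector: the full cohort (control universe).
#' @param min_cases Minimum case count for an analyzable set (default 20).
#' @return List of class `case_control_set`: `phecode`, `case_ids`,
#'   `control_ids`, `n_cases`, `n_controls`, `filtered`.
#' @export
build_case_control <- function(phecode, assignments, map, persons, min_cases = 20) {
  if (!phecode %in% c(map$phecode, unlist(lapply(unique(map$phecode), phecode_ancestors)))) {
    stop_pwmr("build_case_control: phecode %s absent from map", phecode,
              class = "pwmr_validation_error")
  }
  cases <- unique(assignments$person_id[assignments$phecode == phecode])
  excl <- phecode_exclusion_range(phecode, map)
  excluded <- character()
  if (!is.null(excl)) {
    pnum <- as.numeric(assignments$phecode)
    inside <- pnum >= excl[1] & pnum <= excl[2]
    excluded <- unique(assignments$person_id[inside])
  }
  controls <- setdiff(persons, union(cases, excluded))
  structure(list(phecode = phecode, case_ids = cases, control_ids = controls,
                 n_cases = length(cases), n_controls = length(controls),
                 filtered = length(cases) < min_cases),
            class = "case_control_set")
}

#' Build the full phecode phenome
#'
#' One case/control set per distinct assigned phecode; sets below the
#' case-count floor are retained but flagged filtered and skipped by the
#' association scan.
#'
#' @inheritParams build_case_control
#' @return List of class `phenome`: `sets` (named list of
#'   `case_control_set`), `min_cases`, `persons`.
#' @export
build_phenome <- function(assignments, map, persons, min_cases = 20) {
  phecodes <- sort(unique(assignments$phecode))
  sets <- lapply(phecodes, build_case_control, assignments = assignments,
                 map = map, persons = persons, min_cases = min_cases)
  names(sets) <- phecodes
  structure(list(sets = sets, min_cases = min_cases, persons = persons),
            class = "phenome")
}

#' @export
print.phenome <- function(x, ...) {
  eligible <- sum(!vapply(x$sets, `[[`, logical(1), "filtered"))
  cat(sprintf("phenome: %d phecodes (%d with >= %d cases), %d persons\n",
              length(x$sets), eligible, x$min_cases, length(x$persons)))
  invisible(x)
}

# ---- ICD-10 tree ------------------------------------------------------------

#' Build the ICD-10 classification tree over observed codes
#'
#' Nodes are the observed codes plus their ancestors along the ICD-10
#' hierarchy (chapter -> block -> 3-character -> 4-character code); the most
#' specific observed codes are the leaves. Depth is capped at 4-character
#' codes.
#'
#' @param observed_codes Character vector of normalized ICD-10 codes.
#' @param hierarchy Hierarchy table (`code3`, `block`, `chapter`), e.g.
#'   [pwmr_icd_hierarchy()].
#' @return List of class `pheno_tree`: `nodes`, `parent` (named, NA at the
#'   root), `children` (named list), `root`.
#' @export
build_icd_tree <- function(observed_codes, hierarchy = pwmr_icd_hierarchy()) {
  codes <- unique(normalize_icd_code(observed_codes))
  codes3 <- unique(substr(codes, 1, 3))
  missing <- setdiff(codes3, hierarchy$code3)
  if (length(missing)) {
    stop_pwmr("build_icd_tree: no hierarchy entry for code(s) %s",
              paste(missing, collapse = ", "), class = "pwmr_validation_error")
  }
  parent <- c(ROOT = NA_character_)
  add_edge <- function(child, par) {
    if (!child %in% names(parent)) parent[[child]] <<- par
  }
  for (code in codes) {
    c3 <- substr(code, 1, 3)
    h <- hierarchy[match(c3, hierarchy$code3), ]
    add_edge(h$chapter, "ROOT")
    add_edge(h$block, h$chapter)
    add_edge(c3, h$block)
    if (nchar(code) > 3) add_edge(code, c3)
  }
  nodes <- names(parent)
  children <- split(nodes[-1], parent[-1])
  structure(list(nodes = nodes, parent = parent,
                 children = children, root = "ROOT"),
            class = "pheno_tree")
}

tree_subtree_nodes <- function(tree, node) {
  out <- node
  frontier <- node
  while (length(frontier)) {
    kids <- unlist(tree$children[frontier], use.names = FALSE)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Attach per-node case indicator sets to an ICD-10 tree
#'
#' A person is a case at a node if they carry any observed code at or below
#' that node; internal-node case sets are therefore unions of their
#' children's.
#'
#' @param tree A `pheno_tree` from [build_icd_tree()].
#' @param diagnoses A `diagnosis_records` data frame (ICD-10 rows are used).
#' @param persons Full cohort person ids (control universe).
#' @return The tree with added fields `case_ids` (named list per node) and
#'   `persons`.
#' @export
propagate_cases <- function(tree, diagnoses, persons) {
  d10 <- diagnoses[diagnoses$system == "ICD10", , drop = FALSE]
  code_persons <- split(d10$person_id, d10$code)
  code_node <- names(code_persons)
  # Codes observed at 4-char depth attach at their node if present, else at
  # their 3-char ancestor (tree depth cap).
  attach_node <- ifelse(code_node %in% tree$nodes, code_node,
                        substr(code_node, 1, 3))
  tree$case_ids <- lapply(tree$nodes, function(v) {
    sub <- tree_subtree_nodes(tree, v)
    sort(unique(unlist(code_persons[attach_node %in% sub], use.names = FALSE)))
  })
  names(tree$case_ids) <- tree$nodes
  tree$persons <- persons
  tree
}

#' @export
print.pheno_tree <- function(x, ...) {
  leaves <- setdiff(x$nodes, names(x$children))
  cat(sprintf("pheno_tree: %d nodes (%d leaves)%s\n", length(x$nodes),
              length(leaves),
              if (!is.null(x$case_ids)) " with case indicators" else ""))
  invisible(x)
}
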