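# Data model and I/O: parent panels, genetic maps, effect tables,
# recombination fractions.

#' Construct / validate a genetic map
#'
#' A genetic map is a tibble with one row per marker and columns `marker`,
#' `chrom` and `pos_cM`. Rows are sorted by chromosome and position; only
#' distances in centimorgans matter, absolute coordinates carry no meaning.
#'
#' @param x data frame with columns `marker`, `chrom`, `pos_cM`.
#' @return a tibble of class `genetic_map`, sorted by chromosome then position.
#' @examples
#' genetic_map(data.frame(marker = c("m1", "m2"), chrom = 1, pos_cM = c(0, 10)))
#' @export
genetic_map <- function(x) {
  x <- tibble::as_tibble(x)
  assert_that(all(c("marker", "chrom", "pos_cM") %in% names(x)),
              "map needs columns marker, chrom, pos_cM")
  assert_that(!anyNA(x$pos_cM) && all(x$pos_cM >= 0),
              "map positions must be non-negative")
  assert_that(!anyDuplicated(x$marker), "duplicated marker ids in map")
  x <- dplyr::arrange(x, .data$chrom, .data$pos_cM)
  class(x) <- c("genetic_map", class(x))
  x
}

#' Haldane mapping function
#'
#' Converts map distance to recombination fraction assuming no crossover
#' interference: c = (1 - exp(-2 d)) / 2 with d in Morgans.
#'
#' @param d_cM distance in centimorgans (non-negative).
#' @return recombination fraction in [0, 0.5).
#' @export
haldane <- function(d_cM) {
  assert_that(all(d_cM >= 0), "negative map distance")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Pairwise recombination-fraction matrix
#'
#' Builds the marker-by-marker matrix of recombination frequencies used by the
#' LD-propagation variance models. Same-marker entries are 0, markers on
#' different chromosomes assort independently (c = 0.5), within-chromosome
#' entries come from [haldane()].
#'
#' @param map a [genetic_map()] (or a `parent_panel`, whose map is used).
#' @return symmetric numeric matrix with marker ids as dimnames.
#' @export
recombination_matrix <- function(map) {
  if (inherits(map, "parent_panel")) map <- map$map
  map <- genetic_map(map)
  d <- abs(outer(map$pos_cM, map$pos_cM, "-"))
  cmat <- haldane(d)
  same <- outer(map$chrom, map$chrom, "==")
  cmat[!same] <- 0.5
  dimnames(cmat) <- list(map$marker, map$marker)
  cmat
}

# Recombination fraction between consecutive markers in map order; the first
# marker of every chromosome gets 0.5 (fresh random start in the simulator).
adjacent_recomb <- function(map) {
  map <- genetic_map(map)
  nj <- nrow(map)
  cadj <- numeric(nj)
  cadj[1] <- 0.5
  if (nj > 1) {
    d <- diff(map$pos_cM)
    new_chrom <- map$chrom[-1] != map$chrom[-nj]
    cadj[-1] <- ifelse(new_chrom, 0.5, haldane(pmax(d, 0)))
  }
  cadj
}

#' Class-value map: scores assigned to dosage classes
#'
#' Maps each dosage class k = 0..ploidy to an additive score m(k) and a
#' dominance score w(k). The diploid default is the count coding
#' m = (0, 1, 2) with heterozygosity indicator w = (0, 1, 0) (the genotypic
#' parameterization). For autotetraploids no silent default exists; supply the
#' dominance score explicitly, e.g. [dominance_score_polysomic()].
#'
#' @param ploidy even integer >= 2.
#' @param additive numeric vector of length ploidy + 1, additive score per class.
#' @param dominance numeric vector of length ploidy + 1, dominance score per class.
#' @return list of class `class_value_map` with fields `ploidy`, `additive`,
#'   `dominance`.
#' @export
class_value_map <- function(ploidy = 2,
                            additive = 0:ploidy,
                            dominance = NULL) {
  assert_that(is_count(ploidy, 2) && ploidy %% 2 == 0, "ploidy must be an even integer >= 2")
  if (is.null(dominance)) {
    assert_that(ploidy == 2,
                "no default dominance score beyond diploids; supply one (e.g. dominance_score_polysomic())")
    dominance <- c(0, 1, 0)
  }
  assert_that(length(additive) == ploidy + 1 && length(dominance) == ploidy + 1,
              "class scores must cover every dosage class 0..ploidy")
  structure(list(ploidy = ploidy, additive = as.numeric(additive),
                 dominance = as.numeric(dominance)),
            class = "class_value_map")
}

#' Polysomic generalization of the heterozygosity score
#'
#' w(k) = 4 k (ploidy - k) / ploidy^2, proportional to the count of
#' heterozygous allele pairings and equal to the diploid indicator
#' (0, 1, 0) at ploidy 2.
#'
#' @param ploidy even integer >= 2.
#' @return numeric vector of length ploidy + 1.
#' @export
dominance_score_polysomic <- function(ploidy) {
  k <- 0:ploidy
  4 * k * (ploidy - k) / ploidy^2
}

default_cvm <- function(ploidy) {
  if (ploidy == 2) class_value_map(2) else
    stop("supply a class_value_map explicitly for ploidy ", ploidy, call. = FALSE)
}

#' Per-locus trait effects
#'
#' @param additive numeric vector of per-locus additive effects.
#' @param dominance numeric vector of per-locus dominance effects (default 0).
#' @param parameterization `"genotypic"` (additive + dominance components that
#'   may correlate) or `"breeding"` (breeding values + dominance deviations).
#'   The same formulas apply to both; the tag records which scores/effects the
#'   user supplied.
#' @param accuracy prediction accuracy r in [0, 1] attached to these effects.
#' @return list of class `trait_effects`.
#' @export
trait_effects <- function(additive, dominance = NULL,
                          parameterization = c("genotypic", "breeding"),
                          accuracy = 1) {
  parameterization <- match.arg(parameterization)
  if (is.null(dominance)) dominance <- numeric(length(additive))
  assert_that(length(additive) == length(dominance),
              "additive and dominance effect vectors must have equal length")
  assert_that(is.numeric(accuracy) && length(accuracy) == 1 &&
                accuracy >= 0 && accuracy <= 1, "accuracy must be in [0, 1]")
  structure(list(additive = as.numeric(additive),
                 dominance = as.numeric(dominance),
                 parameterization = parameterization,
                 accuracy = accuracy),
            class = "trait_effects")
}

#' Breeding-scheme descriptor
#'
#' Describes how a biparental family is carried to its evaluated generation:
#' `"F1"`/`"CLONE"` evaluate the F1 itself, `"SELF"` applies `t` selfing
#' generations after the F1, `"DH"` derives doubled haploids from F1 gametes
#' (diploids only). An optional tester set turns the evaluated generation into
#' testcross hybrids.
#'
#' @param pipeline one of "F1", "CLONE", "SELF", "DH".
#' @param t number of selfing generations (SELF only), integer >= 0.
#' @param testers optional integer vector of tester parent indices in the panel.
#' @return list of class `cross_scheme`.
#' @export
cross_scheme <- function(pipeline = c("F1", "CLONE", "SELF", "DH"),
                         t = 0L, testers = NULL) {
  pipeline <- match.arg(pipeline)
  assert_that(is_count(t, 0), "t must be a non-negative integer")
  if (pipeline != "SELF") t <- 0L
  if (!is.null(testers)) {
    assert_that(length(testers) >= 1 && all(testers == round(testers)),
                "testers must be parent indices")
  }
  structure(list(pipeline = pipeline, t = as.integer(t), testers = testers),
            class = "cross_scheme")
}

scheme_label <- function(scheme) {
  lab <- switch(scheme$pipeline,
                F1 = "F1", CLONE = "Clonal",
                SELF = paste0("SELF", scheme$t),
                DH = "DH")
  if (!is.null(scheme$testers)) lab <- paste0("Hybrid_", lab)
  lab
}

#' Assemble a parent panel
#'
#' The central data container: an allele-dosage matrix (parents x markers,
#' integers in 0..ploidy counting the effect allele), its genetic map, and
#' optionally phased haplotypes and subpopulation labels.
#'
#' @param dosages integer matrix, parents in rows, markers in columns. Row and
#'   column names identify parents and markers.
#' @param map a [genetic_map()] covering exactly the panel's markers.
#' @param ploidy even integer >= 2 (default 2).
#' @param haplotypes optional list with one `ploidy x n_loci` 0/1 matrix per
#'   parent (1 = effect allele); column sums must reproduce the dosage rows.
#' @param subpop optional character vector of per-parent subpopulation labels.
#' @return list of class `parent_panel` with fields `ploidy`, `dosages`, `map`,
#'   `haplotypes`, `subpop`, plus counts `n_parents` and `n_loci`.
#' @export
parent_panel <- function(dosages, map, ploidy = 2, haplotypes = NULL,
                         subpop = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  assert_that(is_count(ploidy, 2) && ploidy %% 2 == 0, "ploidy must be an even integer >= 2")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("P", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("m", seq_len(ncol(dosages)))
  map <- genetic_map(map)
  missing_in_map <- setdiff(colnames(dosages), map$marker)
  missing_in_panel <- setdiff(map$marker, colnames(dosages))
  if (length(missing_in_map) || length(missing_in_panel)) {
    stop("map/panel marker mismatch; missing in map: ",
         paste(utils::head(missing_in_map, 5), collapse = ", "),
         "; missing in panel: ",
         paste(utils::head(missing_in_panel, 5), collapse = ", "),
         call. = FALSE)
  }
  dosages <- dosages[, map$marker, drop = FALSE]  # map order is canonical
  if (anyNA(dosages))
    stop("missing genotypes are not supported; impute or drop markers upstream",
         call. = FALSE)
  bad <- which(dosages < 0 | dosages > ploidy | dosages != round(dosages),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("dosage out of range 0..%d for parent '%s' at marker '%s'",
                 ploidy, rownames(dosages)[bad[1, 1]],
                 colnames(dosages)[bad[1, 2]]), call. = FALSE)
  }
  if (!is.null(haplotypes)) {
    assert_that(length(haplotypes) == nrow(dosages),
                "need one haplotype matrix per parent")
    haplotypes <- lapply(haplotypes, function(h) {
      h <- as.matrix(h); storage.mode(h) <- "double"; h
    })
    for (i in seq_along(haplotypes)) {
      h <- haplotypes[[i]]
      assert_that(nrow(h) == ploidy && ncol(h) == ncol(dosages),
                  sprintf("haplotype matrix for parent %d has wrong shape", i))
      assert_that(all(h %in% c(0, 1)),
                  sprintf("haplotypes for parent %d must be 0/1", i))
      if (!isTRUE(all.equal(unname(colSums(h)), unname(dosages[i, ])))) {
        stop(sprintf("haplotypes of parent '%s' do not sum to its dosages",
                     rownames(dosages)[i]), call. = FALSE)
      }
    }
    names(haplotypes) <- rownames(dosages)
  }
  if (!is.null(subpop)) {
    assert_that(length(subpop) == nrow(dosages),
                "subpop labels must cover every parent")
    subpop <- as.character(subpop)
  }
  structure(list(ploidy = as.integer(ploidy),
                 dosages = dosages,
                 map = map,
                 haplotypes = haplotypes,
                 subpop = subpop,
                 n_parents = nrow(dosages),
                 n_loci = ncol(dosages)),
            class = "parent_panel")
}

#' @export
print.parent_panel <- function(x, ...) {
  cat(sprintf("<parent_panel> %d parents x %d loci, ploidy %d\n",
              x$n_parents, x$n_loci, x$ploidy))
  cat(sprintf("  chromosomes: %d; phased: %s; subpopulations: %s\n",
              length(unique(x$map$chrom)),
              if (is.null(x$haplotypes)) "no" else "yes",
              if (is.null(x$subpop)) "none" else
                paste(names(table(x$subpop)), table(x$subpop),
                      sep = ":", collapse = ", ")))
  invisible(x)
}

read_table_auto <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Load a parent panel from files
#'
#' @param dosage_path TSV/CSV with parents in rows (first column holds parent
#'   names) and marker ids as remaining column names, integer dosages in cells.
#' @param map_path TSV/CSV with columns `marker`, `chrom`, `pos_cM`.
#' @param phased_path optional VCF with phased genotypes (`|` separator,
#'   2 or 4 alleles per call, ALT = effect allele); sample and marker ids must
#'   match the dosage table.
#' @param ploidy even integer >= 2.
#' @param subpop optional per-parent labels (recycled against dosage rows).
#' @return a [parent_panel()].
#' @export
load_panel <- function(dosage_path, map_path, phased_path = NULL, ploidy = 2,
                       subpop = NULL) {
  tab <- read_table_auto(dosage_path)
  dos <- as.matrix(tab[, -1, drop = FALSE])
  rownames(dos) <- as.character(tab[[1]])
  map <- genetic_map(read_table_auto(map_path))
  haplotypes <- NULL
  if (!is.null(phased_path)) {
    haplotypes <- read_phased_vcf(phased_path, parents = rownames(dos),
                                  markers = map$marker, ploidy = ploidy)
  }
  parent_panel(dos, map, ploidy = ploidy, haplotypes = haplotypes,
               subpop = subpop)
}

# Phased GT matrix from a VCF. Uses VariantAnnotation when available (the
# robust path for real-world files); falls back to a minimal reader for the
# plain uncompressed VCFs this package itself writes.
read_phased_vcf <- function(path, parents, markers, ploidy) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    gt <- suppressWarnings(VariantAnnotation::readGT(path))
    ids <- rownames(gt)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    header <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
    rows <- strsplit(body[-1], "\t")
    ids <- vapply(rows, `[[`, "", 3L)
    smp <- header[-(1:9)]
    gt <- t(vapply(rows, function(r) sub(":.*", "", r[-(1:9)]),
                   character(length(smp))))
    if (length(smp) == 1L) gt <- matrix(gt, ncol = 1L)
    colnames(gt) <- smp
    rownames(gt) <- ids
  }
  assert_that(all(markers %in% rownames(gt)),
              "phased VCF does not cover all panel markers")
  assert_that(all(parents %in% colnames(gt)),
              "phased VCF does not cover all panel parents")
  gt <- gt[markers, parents, drop = FALSE]
  lapply(setNames(parents, parents), function(p) {
    calls <- gt[, p]
    assert_that(!any(grepl("/", calls, fixed = TRUE)),
                sprintf("unphased genotype found for parent '%s'", p))
    alleles <- strsplit(calls, "|", fixed = TRUE)
    assert_that(all(lengths(alleles) == ploidy),
                sprintf("ploidy mismatch in phased calls for parent '%s'", p))
    h <- matrix(as.numeric(unlist(alleles)), nrow = ploidy)
    colnames(h) <- markers
    h
  })
}

#' Write a parent panel to files
#'
#' Inverse of [load_panel()]: `load -> save -> load` is the identity on
#' dosages, map, and haplotypes.
#'
#' @param panel a [parent_panel()].
#' @param dosage_path,map_path output TSV paths.
#' @param phased_path optional output VCF path for phased haplotypes.
#' @return invisibly, the panel.
#' @export
save_panel <- function(panel, dosage_path, map_path, phased_path = NULL) {
  tab <- data.frame(parent = rownames(panel$dosages), panel$dosages,
                    check.names = FALSE)
  utils::write.table(tab, dosage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(panel$map)[, c("marker", "chrom", "pos_cM")],
                     map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(phased_path)) {
    assert_that(!is.null(panel$haplotypes), "panel has no haplotypes to write")
    gt <- vapply(panel$haplotypes, function(h) {
      apply(h, 2, paste, collapse = "|")
    }, character(panel$n_loci))
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(panel$dosages)),
                   collapse = "\t"))
    body <- paste(panel$map$chrom,
                  pmax(1L, as.integer(round(panel$map$pos_cM * 1e4))),
                  panel$map$marker, "A", "T", ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), phased_path)
  }
  invisible(panel)
}

#' Load an effects table
#'
#' @param path TSV/CSV with columns `marker`, `additive`, `dominance`.
#' @param panel panel whose marker order the effects are matched against.
#' @inheritParams trait_effects
#' @return a [trait_effects()] aligned to the panel's marker order.
#' @export
load_effects <- function(path, panel, parameterization = "genotypic",
                         accuracy = 1) {
  tab <- read_table_auto(path)
  assert_that(all(c("marker", "additive", "dominance") %in% names(tab)),
              "effects table needs columns marker, additive, dominance")
  idx <- match(colnames(panel$dosages), tab$marker)
  assert_that(!anyNA(idx), "effects table does not cover all panel markers")
  trait_effects(tab$additive[idx], tab$dominance[idx],
                parameterization = parameterization, accuracy = accuracy)
}

#' Panel diagnostics
#'
#' Report-only checks: monomorphic loci, per-parent heterozygosity, and
#' phasing consistency. Never mutates or rejects the panel.
#'
#' @param panel a [parent_panel()].
#' @return list with `monomorphic` (marker ids with zero dosage variance),
#'   `heterozygosity` (tibble parent/value), and `phasing_consistent`
#'   (logical per parent, or NULL when unphased).
#' @export
validate_panel <- function(panel) {
  colvar <- apply(panel$dosages, 2, var)
  mono <- colnames(panel$dosages)[colvar == 0]
  phi <- panel$ploidy
  het <- rowMeans(panel$dosages != 0 & panel$dosages != phi)
  phasing <- NULL
  if (!is.null(panel$haplotypes)) {
    phasing <- vapply(seq_len(panel$n_parents), function(i) {
      isTRUE(all.equal(unname(colSums(panel$haplotypes[[i]])),
                       unname(panel$dosages[i, ])))
    }, logical(1))
    names(phasing) <- rownames(panel$dosages)
  }
  list(monomorphic = mono,
       heterozygosity = tibble::tibble(parent = rownames(panel$dosages),
                                       heterozygosity = unname(het)),
       phasing_consistent = phasing)
}
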