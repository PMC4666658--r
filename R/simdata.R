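# Synthetic protein families with known truth labels. Each family shares an
# ancestral domain that diverges across species inside variable random
# linkers, surrounded by decoys and paralogs engineered to probe each
# admission rule; this makes every pipeline stage and the optimiser testable
# without any sequence download.

#' Family generator configuration
#'
#' The substitution model is per-site replacement with a uniform choice
#' among the 19 alternative residues (no indels inside the domain; length
#' variation lives entirely in the linkers), so the expected domain identity
#' of species `i` to the ancestor is simply `1 - min(0.9, i * rate)`.
#'
#' @param n_species Number of species-variant homologs.
#' @param domain_length Length of the shared domain in residues.
#' @param linker_length_range Range (min, max) of each terminal linker.
#' @param rate Expected substitutions per site per species step, in
#'   `[0, 0.9]`.
#' @param n_decoys Number of background-composition decoy sequences with a
#'   matched length distribution (so the identity filter, not composition
#'   bias, does the rejecting).
#' @param paralogs Character subset of `c("truncated", "diverged",
#'   "flanking", "reciprocal")`: a truncated paralog shorter than the
#'   domain band, a twilight-zone paralog diverged beyond the identity
#'   threshold, a paralog carrying an extra flanking domain (kept after
#'   trimming by design, hence not part of the default benchmark), and an
#'   in-paralog whose reciprocal best hit is a second source-proteome gene.
#' @param seed Integer seed; identical seeds give byte-identical output
#'   (R's default Mersenne-Twister generator).
#' @param family_id Integer used to prefix accessions.
#' @return A list of class `family_config`.
#' @export
family_config <- function(n_species = 6, domain_length = 150,
                          linker_length_range = c(30, 60), rate = 0.05,
                          n_decoys = 10,
                          paralogs = c("truncated", "diverged",
                                       "reciprocal"),
                          seed = 1, family_id = 1) {
  stopifnot(n_species >= 1, domain_length > 0,
            length(linker_length_range) == 2L,
            linker_length_range[1] >= 0,
            linker_length_range[2] >= linker_length_range[1],
            rate >= 0, rate <= 0.9, n_decoys >= 0)
  stopifnot(all(paralogs %in% c("truncated", "diverged", "flanking",
                                "reciprocal")))
  structure(list(n_species = n_species, domain_length = domain_length,
                 linker_length_range = linker_length_range, rate = rate,
                 n_decoys = n_decoys, paralogs = paralogs,
                 seed = as.integer(seed), family_id = as.integer(family_id)),
            class = "family_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.bg_freqs <- function() .AA_BACKGROUND / sum(.AA_BACKGROUND)

.rand_seq <- function(n) {
  paste(sample(.AA20, n, replace = TRUE, prob = .bg_freqs()), collapse = "")
}

.mutate_seq <- function(residues, p) {
  v <- strsplit(residues, "")[[1]]
  hit <- runif(length(v)) < p
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(a)
      sample(setdiff(.AA20, a), 1L), "")
  }
  paste(v, collapse = "")
}

.linker <- function(range) .rand_seq(sample(range[1]:range[2], 1L))

#' Generate one synthetic protein family
#'
#' Draws an ancestral domain from the background amino-acid distribution,
#' embeds a per-species mutated copy in fresh random linkers, and adds
#' decoys and the configured paralogs. The reference (query) sequence is the
#' ancestor embedded in its own linkers; it is placed in the source
#' proteome, not in the search database. Every generated accession is
#' labelled exactly once in the truth table.
#'
#' @param config A [family_config()].
#' @return A list of class `sim_family` with `queries`, `db`,
#'   `source_proteome` (all [protein_db()]s), `truth` (data.frame
#'   accession/role), `annotations` (an [annotation_table()]) and `config`.
#'   Roles: `reference`, `ortholog` (species variants), `decoy`,
#'   `paralog_truncated`, `paralog_diverged`, `paralog_flanking`,
#'   `paralog_reciprocal`, `source_gene`, `source_decoy`.
#' @export
generate_family <- function(config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  .with_seed(config$seed, {
    fid <- sprintf("F%03d", config$family_id)
    rng <- config$linker_length_range
    ancestor <- .rand_seq(config$domain_length)
    mk <- function(acc, domain, organism, desc,
                   left = .linker(rng), right = .linker(rng)) {
      sequence_record(acc, paste0(left, domain, right), desc, organism)
    }

    reference <- mk(paste0(fid, "_REF"), ancestor, "species_0",
                    paste0("reference query OS=species_0"))
    variants <- lapply(seq_len(config$n_species), function(i) {
      mk(paste0(fid, "_S", i),
         .mutate_seq(ancestor, min(0.9, i * config$rate)),
         paste0("species_", i),
         paste0("family homolog OS=species_", i))
    })

    fam_len <- nchar(reference$residues)
    len_range <- range(c(fam_len, vapply(variants, function(v)
      nchar(v$residues), 0L)))
    decoys <- lapply(seq_len(config$n_decoys), function(j) {
      sequence_record(paste0(fid, "_DEC", j),
                      .rand_seq(sample(len_range[1]:len_range[2], 1L)),
                      paste0("background decoy OS=species_", j %% 3 + 1),
                      paste0("species_", j %% 3 + 1))
    })

    db_recs <- c(variants, decoys)
    roles <- c(rep("ortholog", length(variants)),
               rep("decoy", length(decoys)))
    src_recs <- list(reference)
    src_roles <- "reference"

    if ("truncated" %in% config$paralogs) {
      # shares the domain's first part at high identity but is far shorter
      # than the family band: rejected by the length filter
      frag <- .mutate_seq(substr(ancestor, 1L,
                                 max(20L, config$domain_length %/% 3)), 0.05)
      db_recs <- c(db_recs, list(mk(paste0(fid, "_PTRUNC"), frag,
                                    "species_1", "truncated paralog",
                                    left = .rand_seq(3), right = .rand_seq(3))))
      roles <- c(roles, "paralog_truncated")
    }
    if ("diverged" %in% config$paralogs) {
      # twilight-zone paralog: same architecture, domain identity ~45%,
      # below the default Rost threshold but easily within the e-value cut
      db_recs <- c(db_recs, list(mk(paste0(fid, "_PDIV"),
                                    .mutate_seq(ancestor, 0.55),
                                    "species_2", "diverged paralog")))
      roles <- c(roles, "paralog_diverged")
    }
    if ("flanking" %in% config$paralogs) {
      # extra terminal domain well beyond m: kept but trimmed
      extra <- .rand_seq(3 * 28 + 6)
      db_recs <- c(db_recs, list(mk(paste0(fid, "_PFLANK"),
                                    .mutate_seq(ancestor, 0.1),
                                    "species_3", "flanking-domain paralog",
                                    right = paste0(.linker(rng), extra))))
      roles <- c(roles, "paralog_flanking")
    }
    if ("reciprocal" %in% config$paralogs) {
      # gene2 is a second source-proteome gene; the in-paralog in the
      # search database is closer to gene2 than to the reference, so its
      # reciprocal best hit is gene2: homolog yes, ortholog no
      gene2_domain <- .mutate_seq(ancestor, 0.12)
      src_recs <- c(src_recs, list(mk(paste0(fid, "_GENE2"), gene2_domain,
                                      "species_0", "paralogous source gene")))
      src_roles <- c(src_roles, "source_gene")
      db_recs <- c(db_recs, list(mk(paste0(fid, "_PRECIP"),
                                    .mutate_seq(gene2_domain, 0.03),
                                    "species_1", "reciprocal in-paralog")))
      roles <- c(roles, "paralog_reciprocal")
    }

    src_dec <- lapply(1:5, function(j) {
      sequence_record(paste0(fid, "_SRCDEC", j),
                      .rand_seq(sample(len_range[1]:len_range[2], 1L)),
                      "source-proteome decoy", "species_0")
    })
    src_recs <- c(src_recs, src_dec)
    src_roles <- c(src_roles, rep("source_decoy", length(src_dec)))

    truth <- data.frame(
      accession = c(reference$accession,
                    vapply(db_recs, `[[`, "", "accession"),
                    vapply(src_recs[-1], `[[`, "", "accession")),
      role = c("reference", roles, src_roles[-1]),
      stringsAsFactors = FALSE)

    fam_members <- c(reference$accession,
                     vapply(variants, `[[`, "", "accession"),
                     truth$accession[grepl("^paralog", truth$role)])
    annot_ids <- c(fam_members,
                   vapply(decoys, `[[`, "", "accession"))
    ann <- annotation_table(
      annot_ids,
      pfam = lapply(annot_ids, function(a)
        if (a %in% fam_members) paste0("PF_", fid) else character()),
      kegg = lapply(annot_ids, function(a)
        if (a %in% c(reference$accession,
                     vapply(variants, `[[`, "", "accession")))
          paste0("path_", fid) else character()),
      go = lapply(annot_ids, function(a) {
        if (!(a %in% fam_members)) {
          return(data.frame(term = character(), evidence = character(),
                            stringsAsFactors = FALSE))
        }
        df <- data.frame(term = paste0("GO:", fid, "_iea"),
                         evidence = "IEA", stringsAsFactors = FALSE)
        if (!grepl("PDIV|PTRUNC", a)) {
          df <- rbind(df, data.frame(term = paste0("GO:", fid, "_proc"),
                                     evidence = "EXP",
                                     stringsAsFactors = FALSE))
        }
        df
      }))

    structure(list(queries = protein_db(list(reference),
                                        name = paste0(fid, "_queries")),
                   db = protein_db(db_recs, name = paste0(fid, "_db")),
                   source_proteome = protein_db(src_recs,
                                                name = paste0(fid, "_src")),
                   truth = truth, annotations = ann, config = config),
              class = "sim_family")
  })
}

#' Truth accession sets of a simulated family
#'
#' The homolog truth comprises the species variants plus the reciprocal
#' in-paralog (a genuine homolog that merely fails reciprocity); the
#' ortholog truth is the species variants alone. Decoys and the truncated /
#' diverged paralogs are intended rejections at the default operating
#' point.
#'
#' @param fam A `sim_family` (or its `truth` data.frame).
#' @return A list with `homologs` and `orthologs` character vectors.
#' @export
truth_sets <- function(fam) {
  truth <- if (is.data.frame(fam)) fam else fam$truth
  list(homologs = truth$accession[truth$role %in%
                                    c("ortholog", "paralog_reciprocal")],
       orthologs = truth$accession[truth$role == "ortholog"])
}

#' Generate a labelled benchmark of independent families
#'
#' @param n_families Number of families.
#' @param config Template [family_config()]; its `seed` and `family_id` are
#'   overridden per family with seeds derived from `seed`.
#' @param seed Master seed.
#' @return A list of class `sim_benchmark` with `families` (list of
#'   `sim_family`), `n_families` and `seed`.
#' @export
generate_benchmark <- function(n_families = 20, config = family_config(),
                               seed = 1) {
  stopifnot(n_families >= 1)
  families <- lapply(seq_len(n_families), function(i) {
    cfg <- config
    cfg$seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %%
                             2147483647)
    cfg$family_id <- i
    generate_family(cfg)
  })
  structure(list(families = families, n_families = n_families, seed = seed),
            class = "sim_benchmark")
}

#' @export
print.sim_benchmark <- function(x, ...) {
  cat(sprintf("<sim_benchmark> %d families (seed %s)\n", x$n_families,
              format(x$seed)))
  invisible(x)
}

#' Benchmark items for the optimiser
#'
#' @param bench A [generate_benchmark()] result.
#' @return A list of `list(queries, db, truth)` items, with `truth` the
#'   homolog truth accessions, as consumed by [optimize_parameters()].
#' @export
benchmark_items <- function(bench) {
  lapply(bench$families, function(f) {
    list(queries = f$queries, db = f$db, truth = truth_sets(f)$homologs)
  })
}

#' Run the pipeline over a benchmark and score it
#'
#' Runs [find_homologs()] (and [classify_orthologs()]) on every family with
#' the given parameters and pools the confusion counts against the planted
#' truth.
#'
#' @param bench A [generate_benchmark()] result.
#' @param params [search_params()].
#' @return A list with `homologs` and `orthologs`, each an
#'   [accuracy_report][evaluate].
#' @export
evaluate_benchmark <- function(bench, params = search_params()) {
  hc <- oc <- c(tp = 0L, fp = 0L, fn = 0L)
  for (f in bench$families) {
    ts <- truth_sets(f)
    hres <- find_homologs(f$queries, f$db, params)
    pred_h <- setdiff(hres$members$accession, hres$reference_id)
    cc <- confusion_counts(pred_h, ts$homologs)
    hc <- hc + c(tp = cc$tp, fp = cc$fp, fn = cc$fn)
    ores <- classify_orthologs(hres, f$source_proteome, params)
    co <- confusion_counts(ores$members$accession, ts$orthologs)
    oc <- oc + c(tp = co$tp, fp = co$fp, fn = co$fn)
  }
  list(homologs = evaluate(eval_counts(hc["tp"], hc["fp"], hc["fn"])),
       orthologs = evaluate(eval_counts(oc["tp"], oc["fp"], oc["fn"])))
}

#' Write a benchmark to a directory of plain-text files
#'
#' Pools all families into `queries.fasta`, `db.fasta`,
#' `source_proteome.fasta`, `truth.tsv` (accession, role, family) and
#' `annotations.tsv`, plus a `manifest.yaml` listing every file and the
#' per-family accession counts.
#'
#' @param bench A [generate_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- function(part) {
    recs <- unlist(lapply(bench$families, function(f) .db_records(f[[part]])),
                   recursive = FALSE)
    protein_db(recs, name = part)
  }
  write_fasta(pool("queries"), file.path(dir, "queries.fasta"))
  write_fasta(pool("db"), file.path(dir, "db.fasta"))
  write_fasta(pool("source_proteome"),
              file.path(dir, "source_proteome.fasta"))
  truth <- do.call(rbind, lapply(seq_along(bench$families), function(i) {
    cbind(bench$families[[i]]$truth, family = i)
  }))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ann_all <- bench$families[[1]]$annotations
  for (f in bench$families[-1]) {
    extra <- f$annotations
    ann_all <- structure(c(unclass(ann_all), unclass(extra)),
                         class = "annotation_table")
  }
  write_annotation_table(ann_all, file.path(dir, "annotations.tsv"))
  yaml::write_yaml(list(
    n_families = bench$n_families, seed = bench$seed,
    files = c("queries.fasta", "db.fasta", "source_proteome.fasta",
              "truth.tsv", "annotations.tsv"),
    families = lapply(bench$families, function(f)
      list(reference = f$truth$accession[f$truth$role == "reference"],
           n_records = nrow(f$truth)))),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}
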