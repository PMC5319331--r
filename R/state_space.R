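## Adult stage table: dormant (size 0), vegetative sizes 1..m, flowering
## sizes 1..m, giving 2m + 1 mature states per year.
adult_stage_table <- function(max_size) {
  data.frame(
    stage_id = seq_len(2 * max_size + 1),
    name = c("D", paste0("V", seq_len(max_size)), paste0("F", seq_len(max_size))),
    size = c(0, seq_len(max_size), seq_len(max_size)),
    flowering = c(0, rep(0, max_size), rep(1, max_size))
  )
}

new_state_space <- function(design, states, max_size, stage_tab, target,
                            juv_arcs, fec_to, entry_stages, n_ages = NA) {
  states$idx <- seq_len(nrow(states))
  structure(list(design = design, states = states, n = nrow(states),
                 max_size = max_size, stage_tab = stage_tab, target = target,
                 juv_arcs = juv_arcs, fec_to = fec_to,
                 entry_stages = entry_stages, n_ages = n_ages),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state space (%s design): %d states, adult max size %d\n",
              x$design, x$n, x$max_size))
  invisible(x)
}

## juvenile arc record: from, to, surv (name of juvenile survival
## parameter), branch ("none", "sprout<b>", or an entry stage name)
juv_arc <- function(from, to, surv, branch = "none") {
  data.frame(from = from, to = to, surv = surv, branch = branch)
}

#' Historical (stage-pair) state space
#'
#' States are ordered pairs (stage in year t-1, stage in year t). Adults
#' occupy one of `2 * max_size + 1` mature states (dormant, vegetative
#' sizes 1..max, flowering sizes 1..max); all ordered adult pairs are
#' states. The juvenile pathway contributes additional pair states. With
#' `juvenile = "full"` the pathway is: a fixed path
#' seed -> protocorm 1 -> 2 -> 3 -> new seedling (4 pairs), emergence of
#' the new seedling as a year-1 seedling with 0, 1 or 2 sprouts (3 pairs),
#' year-1 to year-2 seedling (9 pairs), and entry of year-2 seedlings into
#' the 6 designated adult entry stages (18 pairs): 34 juvenile pairs.
#' With `max_size = 9` (19 adult stages) the space has
#' `361 + 34 = 395` states. `juvenile = "simple"` gives a compact pathway
#' (one seedling state plus seedling-to-entry pairs) used for small test
#' spaces.
#'
#' Transitions obey the chaining rule: a pair (i, j) may only move to a
#' pair (j, k).
#'
#' @param max_size Maximum adult size (sprout count).
#' @param entry_stages Names of the adult entry stages reachable from the
#'   last seedling stage (first must be the dormant stage `"D"`).
#' @param juvenile `"full"` or `"simple"` juvenile pathway.
#' @return A `state_space` object.
#' @export
historical_state_space <- function(max_size = 9,
                                   entry_stages = c("D", "V1", "V2", "F1", "F2", "V3"),
                                   juvenile = c("full", "simple")) {
  juvenile <- match.arg(juvenile)
  stg <- adult_stage_table(max_size)
  if (!all(entry_stages %in% stg$name))
    ss_stop("invalid_argument", "entry stages must be adult stage names")
  if (entry_stages[1] != "D")
    ss_stop("invalid_argument", "first entry stage must be dormant ('D')")
  S <- nrow(stg)
  eid <- match(entry_stages, stg$name)
  ne <- length(entry_stages)

  st <- function(cp, sp, fp, cc, sc, fc, nm)
    data.frame(name = nm, class_prev = cp, size_prev = sp, flw_prev = fp,
               class_cur = cc, size_cur = sc, flw_cur = fc, age = NA_real_)

  states <- NULL
  arcs <- NULL
  if (juvenile == "full") {
    path <- rbind(
      st("seed", 0, 0, "protocorm1", 0, 0, "seed>p1"),
      st("protocorm1", 0, 0, "protocorm2", 0, 0, "p1>p2"),
      st("protocorm2", 0, 0, "protocorm3", 0, 0, "p2>p3"),
      st("protocorm3", 0, 0, "newseedling", 0, 0, "p3>ns"))
    ns_sdl <- do.call(rbind, lapply(0:2, function(b)
      st("newseedling", 0, 0, "seedling1", b, 0, paste0("ns>sdl1_", b))))
    sdl12 <- do.call(rbind, lapply(0:2, function(a) do.call(rbind, lapply(0:2, function(b)
      st("seedling1", a, 0, "seedling2", b, 0, paste0("sdl1_", a, ">sdl2_", b))))))
    entry <- do.call(rbind, lapply(0:2, function(b) do.call(rbind, lapply(seq_len(ne), function(e)
      st("seedling2", b, 0, "adult", stg$size[eid[e]], stg$flowering[eid[e]],
         paste0("sdl2_", b, ">", entry_stages[e]))))))
    states <- rbind(path, ns_sdl, sdl12, entry)
    n_juv <- nrow(states)  # 4 + 3 + 9 + 18 = 34
    arcs <- rbind(
      juv_arc(1, 2, "s_protocorm1"),
      juv_arc(2, 3, "s_protocorm2"),
      juv_arc(3, 4, "s_protocorm3"),
      do.call(rbind, lapply(0:2, function(b)
        juv_arc(4, 5 + b, "s_newseedling", paste0("sprout", b)))),
      do.call(rbind, lapply(0:2, function(a) do.call(rbind, lapply(0:2, function(b)
        juv_arc(5 + a, 8 + a * 3 + b, "s_seedling", paste0("sprout", b)))))),
      do.call(rbind, lapply(0:2, function(a) do.call(rbind, lapply(0:2, function(b)
        do.call(rbind, lapply(seq_len(ne), function(e)
          juv_arc(8 + a * 3 + b, 17 + b * ne + (e - 1), "s_seedling",
                  entry_stages[e])))))))
    )
    arcs <- unique(arcs)
    entry_pair_cur <- rep(eid, times = 3)          # cur adult stage of states 17..34
    entry_first <- 17L
  } else {
    states <- st("seed", 0, 0, "seedling", 0, 0, "sdl")
    entry <- do.call(rbind, lapply(seq_len(ne), function(e)
      st("seedling", 0, 0, "adult", stg$size[eid[e]], stg$flowering[eid[e]],
         paste0("sdl>", entry_stages[e]))))
    states <- rbind(states, entry)
    n_juv <- nrow(states)  # 1 + ne
    arcs <- do.call(rbind, lapply(seq_len(ne), function(e)
      juv_arc(1, 1 + e, "s_seedling", entry_stages[e])))
    entry_pair_cur <- eid
    entry_first <- 2L
  }

  adult <- do.call(rbind, lapply(seq_len(S), function(i) do.call(rbind, lapply(seq_len(S), function(j)
    st("adult", stg$size[i], stg$flowering[i], "adult", stg$size[j], stg$flowering[j],
       paste0(stg$name[i], ">", stg$name[j]))))))
  states <- rbind(states, adult)
  n <- nrow(states)

  ## target matrix: adult-current source (pair (., j)) moving to stage s
  ## lands in pair (j, s)
  target <- matrix(NA_integer_, n, S)
  cur_stage <- rep(NA_integer_, n)
  cur_stage[seq(entry_first, length.out = length(entry_pair_cur))] <- entry_pair_cur
  ad_idx <- n_juv + seq_len(S * S)
  cur_stage[ad_idx] <- rep(seq_len(S), times = S)[order(rep(seq_len(S), each = S) * 0 + 1)]
  cur_stage[ad_idx] <- rep(seq_len(S), S)[seq_len(S * S)]
  # pair (i, j): index n_juv + (i-1)*S + j, so cur stage cycles fastest
  cur_stage[ad_idx] <- rep(seq_len(S), times = S)
  for (src in which(!is.na(cur_stage))) {
    j <- cur_stage[src]
    target[src, ] <- n_juv + (j - 1L) * S + seq_len(S)
  }
  states$cur_stage <- cur_stage

  new_state_space("historical", states, max_size, stg, target, arcs,
                  fec_to = 1L, entry_stages = entry_stages)
}

#' Cypripedium-design historical state space
#'
#' The historical stage-pair space with 19 mature states (one to nine
#' sprouts, vegetative or flowering, plus dormancy) paired across
#' consecutive years, and the full juvenile pathway:
#' `19 x 19 + 34 = 395` states.
#'
#' @inheritParams historical_state_space
#' @return A `state_space` of order 395.
#' @export
cypripedium_state_space <- function(entry_stages = c("D", "V1", "V2", "F1", "F2", "V3")) {
  historical_state_space(max_size = 9, entry_stages = entry_stages, juvenile = "full")
}

#' Age-by-stage state space
#'
#' Adults occupy `n_ages` age classes (the final class absorbing, to model
#' stasis in old adults) crossed with `2 * max_size + 1` mature states;
#' juveniles occupy `n_juv` unmonitored stages (two protocorm stages and
#' one seedling stage in the full design). Transitions increment age (or
#' hold at the final class); fecundity arcs run from flowering states to
#' the first juvenile stage.
#'
#' @param n_ages Number of adult age classes (final class absorbing).
#' @param max_size Maximum adult size (leaf count).
#' @param n_juv Number of juvenile stages (3 = protocorm 1, protocorm 2,
#'   seedling; 1 = seedling only, for small test spaces).
#' @param entry_stages Adult stages a seedling can enter (first must be
#'   `"D"`).
#' @return A `state_space` object.
#' @export
agestage_state_space <- function(n_ages = 10, max_size = 8, n_juv = 3,
                                 entry_stages = c("D", "V1", "V2", "F1")) {
  stg <- adult_stage_table(max_size)
  if (!all(entry_stages %in% stg$name)) ss_stop("invalid_argument", "bad entry stages")
  if (entry_stages[1] != "D") ss_stop("invalid_argument", "first entry stage must be 'D'")
  if (!n_juv %in% c(1, 3)) ss_stop("invalid_argument", "n_juv must be 1 or 3")
  S <- nrow(stg)
  eid <- match(entry_stages, stg$name)

  juv_classes <- if (n_juv == 3) c("protocorm1", "protocorm2", "seedling") else "seedling"
  jst <- data.frame(name = juv_classes, class_prev = NA, size_prev = NA,
                    flw_prev = NA, class_cur = juv_classes, size_cur = 0,
                    flw_cur = 0, age = NA_real_)
  ast <- do.call(rbind, lapply(seq_len(n_ages), function(a)
    data.frame(name = paste0("a", a, "_", stg$name), class_prev = NA,
               size_prev = NA, flw_prev = NA, class_cur = "adult",
               size_cur = stg$size, flw_cur = stg$flowering, age = a)))
  states <- rbind(jst, ast)
  n <- nrow(states)

  target <- matrix(NA_integer_, n, S)
  cur_stage <- rep(NA_integer_, n)
  for (a in seq_len(n_ages)) {
    src <- n_juv + (a - 1L) * S + seq_len(S)
    a2 <- min(a + 1L, n_ages)
    cur_stage[src] <- seq_len(S)
    target[src, ] <- matrix(n_juv + (a2 - 1L) * S + seq_len(S), length(src), S,
                            byrow = TRUE)
  }
  states$cur_stage <- cur_stage

  sdl <- n_juv  # index of the seedling stage
  arcs <- do.call(rbind, lapply(seq_along(eid), function(e)
    juv_arc(sdl, n_juv + eid[e], "s_seedling", entry_stages[e])))
  if (n_juv == 3) {
    arcs <- rbind(juv_arc(1, 2, "s_protocorm1"),
                  juv_arc(2, 3, "s_protocorm2"), arcs)
  }
  new_state_space("agestage", states, max_size, stg, target, arcs,
                  fec_to = 1L, entry_stages = entry_stages, n_ages = n_ages)
}

#' Ophrys-design age-by-stage state space
#'
#' Ten adult age classes (stasis in the tenth) by 17 mature states (one to
#' eight leaves, vegetative or flowering, plus dormancy) plus two
#' protocorm stages and one seedling stage: `170 + 3 = 173` states.
#'
#' @inheritParams agestage_state_space
#' @return A `state_space` of order 173.
#' @export
ophrys_state_space <- function(entry_stages = c("D", "V1", "V2", "F1")) {
  agestage_state_space(n_ages = 10, max_size = 8, n_juv = 3,
                       entry_stages = entry_stages)
}

#' Simple (ahistorical) state space
#'
#' One seedling stage plus the `2 * max_size + 1` adult stages, with no
#' history or age structure; used for toy models and fixtures.
#'
#' @inheritParams agestage_state_space
#' @return A `state_space` object.
#' @export
simple_state_space <- function(max_size = 3, entry_stages = c("D", "V1", "V2")) {
  stg <- adult_stage_table(max_size)
  if (!all(entry_stages %in% stg$name)) ss_stop("invalid_argument", "bad entry stages")
  if (entry_stages[1] != "D") ss_stop("invalid_argument", "first entry stage must be 'D'")
  S <- nrow(stg)
  eid <- match(entry_stages, stg$name)
  states <- rbind(
    data.frame(name = "sdl", class_prev = NA, size_prev = NA, flw_prev = NA,
               class_cur = "seedling", size_cur = 0, flw_cur = 0, age = NA_real_),
    data.frame(name = stg$name, class_prev = NA, size_prev = NA, flw_prev = NA,
               class_cur = "adult", size_cur = stg$size, flw_cur = stg$flowering,
               age = NA_real_))
  n <- nrow(states)
  target <- matrix(NA_integer_, n, S)
  cur_stage <- c(NA_integer_, seq_len(S))
  target[1 + seq_len(S), ] <- matrix(1L + seq_len(S), S, S, byrow = TRUE)
  states$cur_stage <- cur_stage
  arcs <- do.call(rbind, lapply(seq_along(eid), function(e)
    juv_arc(1, 1 + eid[e], "s_seedling", entry_stages[e])))
  new_state_space("simple", states, max_size, stg, target, arcs,
                  fec_to = 1L, entry_stages = entry_stages)
}

## covariate data frame for adult-current source states
state_covariates <- function(space) {
  s <- space$states
  ad <- which(!is.na(s$cur_stage))
  cov <- data.frame(row.names = NULL,
                    siz_t = s$size_cur[ad], flwyn_t = s$flw_cur[ad])
  if (space$design == "historical") {
    cov$siz_tm1 <- ifelse(is.na(s$size_prev[ad]), 0, s$size_prev[ad])
    cov$flwyn_tm1 <- ifelse(is.na(s$flw_prev[ad]), 0, s$flw_prev[ad])
    cov$grw_t <- cov$siz_t - cov$siz_tm1
  } else if (space$design == "agestage") {
    cov$age <- s$age[ad]
  }
  list(idx = ad, cov = cov)
}

#' Admissible arcs of a state space
#'
#' Enumerates every structurally admissible transition: survival
#' transitions respecting the historical chaining rule ((i,j) can only
#' reach (j,k)) or the age-increment rule, juvenile-pathway arcs, and
#' fecundity arcs from flowering states to the first juvenile state.
#'
#' @param space A `state_space`.
#' @return Data frame with columns `from`, `to`, `type`.
#' @export
admissible_arcs <- function(space) {
  if (!inherits(space, "state_space")) ss_stop("validation_error", "not a state space")
  res <- list()
  ad <- which(!is.na(space$states$cur_stage))
  if (length(ad)) {
    res$tr <- data.frame(
      from = rep(ad, each = ncol(space$target)),
      to = as.integer(t(space$target[ad, , drop = FALSE])),
      type = "transition")
  }
  if (!is.null(space$juv_arcs) && nrow(space$juv_arcs)) {
    res$juv <- data.frame(from = space$juv_arcs$from, to = space$juv_arcs$to,
                          type = "juvenile")
  }
  fec_from <- which(space$states$flw_cur == 1)
  if (length(fec_from)) {
    res$fec <- data.frame(from = fec_from, to = space$fec_to, type = "fecundity")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a state space index as CSV
#'
#' Writes one row per state (index, name, current/previous stage fields,
#' age) so matrix exports can be labelled; `read_state_index` reads it
#' back.
#'
#' @param space A `state_space`.
#' @param path File path.
#' @export
write_state_index <- function(space, path) {
  write.csv(space$states, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_index
#' @export
read_state_index <- function(path) read.csv(path)
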