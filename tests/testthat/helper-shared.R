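# Shared (memoized) expensive fixtures so several test files can reuse one
# identification/clustering run.

.sharedEnv <- new.env(parent = emptyenv())

sharedSingleChannel <- function() {
  if (is.null(.sharedEnv$single)) {
    fx <- makeShellEnsemble(channels = list(list(direction = c(0, 0, 1),
                                                 schedule = 1.5)),
                            frames = 1)
    ens <- assignRadii(fx$ensemble)
    ris <- buildRIS(ens, 1, ballsPerAtom = 12, seed = 1)
    graph <- buildVoronoiGraph(ris)
    params <- searchParams()
    labeling <- labelVertices(graph, params)
    sv <- optimizeStart(graph, c(0, 0, 0), params@startMaxDist,
                        params@startMinClearance)
    pws <- findPathways(graph, ris, labeling, sv$vertex, params, 1L)
    .sharedEnv$single <- list(fx = fx, ensemble = ens, ris = ris,
                              graph = graph, params = params,
                              labeling = labeling, start = sv,
                              pathways = pws)
  }
  .sharedEnv$single
}

sharedTwoChannelRun <- function() {
  if (is.null(.sharedEnv$two)) {
    fx <- makeShellEnsemble(channels = list(
      list(direction = c(0, 0, 1), schedule = c(1.5, 0.5, 1.5, 0.5)),
      list(direction = c(sin(pi / 3), 0, cos(pi / 3)), schedule = 1.2)),
      frames = 4)
    ens <- assignRadii(fx$ensemble)
    run <- identifyTunnels(ens, searchParams(), xyz = c(0, 0, 0), seed = 1)
    run <- clusterTunnels(run, threshold = 3.5)
    .sharedEnv$two <- list(fx = fx, run = run)
  }
  .sharedEnv$two
}
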