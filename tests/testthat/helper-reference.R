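# Frozen terminal wavelet-packet coefficients (level 3, periodization,
# frequency order) of the closed-form test signal below, computed with an
# independent reference implementation (PyWavelets 1.9.0, WaveletPacket with
# mode "periodization", get_level(3, order = "freq")) and frozen here so the
# suite runs without that dependency. 64 values per basis: 8 bands x 8
# coefficients, concatenated in band order.

reference_signal_64 <- function() {
  i <- 0:63
  sin(2 * pi * 7 * i / 64) + 0.5 * cos(2 * pi * 3 * i / 64) + 0.1 * i / 64
}

reference_wpt_level3 <- list(
   db4 = c(-0.8278369367764786, 0.4192057582859556, 0.8341849869119392, -1.265323164265971, 1.124842354307083, -0.03348883451629764, -0.6345910026512308, 1.496700019073813, -2.853777410826122, -1.245026343300206, 0.2406105645322857, 1.368796307821921, 2.883019035342695, 1.241906317005377, -0.2456007277078692, -1.360907662817209, -0.8555855452645255, -1.51508419518003, -1.250738028371666, -0.3095067977491489, 0.8592891965106797, 1.516343033592682, 1.205543296513893, 0.2885893118928672, -0.0205856287024434, -0.04479196015856055, 0.03571195760728242, -0.03426309402892355, -0.02404134737198871, 0.04607508611154443, -0.03977656304078442, 0.04655430204393457, -0.001528890982586972, -0.0002474655278910873, -0.0009364529455457397, -0.0002874662387596406, 0.0001334960594535466, 0.0005612899194524441, 0.001921928461540889, -0.003712647385251986, -0.1011370674573839, -0.07473187118492169, -0.004255382117849918, 0.06874802205785166, 0.1013400939141067, 0.07178067455367974, 0.009721617996484098, -0.06951199352764199, -0.07822457928255301, 0.03221771446077193, 0.1336876746516051, 0.1531875281990127, 0.08303601967472028, -0.03347635952526384, -0.1428992578121988, -0.1678935931358267, -0.0003328317184100081, 0.01467681604808807, 0.0009299985559529725, 0.002282941130217115, -0.002112911965869936, 0.004191333937150831, -0.0009953461935700673, -0.0009623302638940984),
   sym3 = c(-0.4234618637766195, 1.412544858601413, -0.9712130436154599, 0.3146682302454247, 0.8119701396811402, -1.170598766039665, 1.180754366320631, -0.04097074104792309, -0.7554327387592605, 0.8950358212622874, 2.810189951819094, 1.481306984685918, 0.7324749403323407, -0.8841309446405713, -2.808945067550227, -1.411670366310865, 1.58595429036911, 1.048847397117355, -0.1908753489241854, -1.197221551211687, -1.586214968654628, -1.048430133454283, 0.1820170457954535, 1.187430914005793, 0.115938454002296, -0.08914636218095834, 0.03233964857303656, -0.02640791655360436, -0.09784999686182991, 0.09308692265675783, -0.03140164799348166, 0.02255291330926817, 0.02456589840769244, -0.0006882730757914735, 0.003342681377865052, 0.003247120223022933, 0.003465687737311975, -0.0008586284688758827, -0.003579386842033294, 0.0002493267472279646, -0.170609931351089, -0.1024017851527439, 0.03102276088432995, 0.1454089056538923, 0.1744324090179623, 0.1022379846454827, -0.02878735847896826, -0.1667709460572942, 0.04325017212859996, -0.1436505612151988, -0.2585370799080548, -0.2097823707611936, -0.04027921468406982, 0.142841107067721, 0.2554022219234463, 0.1798045853742671, -0.002227633572478273, -0.02262662715108508, -0.004507209139478637, 0.007055941083696757, -0.009580850188311264, 0.0149822926365883, 0.004839157432651377, -0.00561274063361179),
   coif2 = c(-0.317067204968453, 1.35268581498633, -1.138196306929615, 0.4612494640843553, 0.7001040020003874, -1.123327526002399, 1.352223296285142, -0.1739783590869343, 0.7686439010610188, -0.7015102239382485, -2.766218372648211, -1.776300756650429, -0.7579276834385691, 0.6964935321223834, 2.776460104594893, 1.70014519732026, 1.462664645644964, 0.8289742547085386, -0.3329126121973723, -1.286460788477895, -1.462033795734825, -0.8267200299313554, 0.3133240353143371, 1.279160031380063, -0.06566378796396612, 0.03403411005352476, 0.01852851014565169, -0.0355251626571533, 0.03871450005012168, -0.03578504679009805, -0.0200019611865545, 0.04211686527828257, 0.02550699390128473, -0.00269332364697706, 0.0005476295646643424, -0.0004550030515422403, -0.0007723703018198656, -0.0003502106484130961, -0.0004969197862077621, 0.00505500622544695, 0.03076408643046917, -0.03787846624573882, -0.08636859648451436, -0.08414514482999738, -0.03284235770133596, 0.03793325895888894, 0.08103065471480958, 0.09771537352123359, -0.09127028531829548, -0.144356005670334, -0.1133723278770826, -0.01840478781345655, 0.09074405831618174, 0.1436431409753195, 0.1141938874564953, -0.008736419518864684, 0.01102799680055255, 0.006636095748102132, 0.001381767710897244, -0.004146110987594378, 0.0007901056706053886, 0.001265877900487894, -0.001858743627852976, 0.002580680314466935))

# The reference implementation derives its high-pass filter with the opposite
# sign (g[k] = (-1)^(k+1) h[L-1-k]); this package follows the QMF relation
# g[k] = (-1)^k h[L-1-k]. A band reached through an odd number of high-pass
# steps therefore has all coefficient signs flipped relative to the reference;
# align the frozen values to this package's convention (energies and
# reconstructions are identical under either convention).
local({
  sign_of_band <- vapply(0:7, function(f) {
    natural <- bitwXor(f, bitwShiftR(f, 1L))          # freq -> Paley index
    d_steps <- sum(bitwAnd(natural, c(1L, 2L, 4L)) > 0)  # high-pass count
    (-1)^d_steps
  }, numeric(1))
  flip <- rep(sign_of_band, each = 8L)
  reference_wpt_level3 <<- lapply(reference_wpt_level3, function(v) v * flip)
})
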