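fine,group
Acropora abrotanoides,Acropora abrotanoides
Acropora cf. valida,Scleractinia
Acropora sp.,Scleractinia
Isopora sp.,Scleractinia
Montipora sp.,Scleractinia
Astreopora sp.,Scleractinia
Porites rus,Scleractinia
Porites lutea,Scleractinia
Pocillopora damicornis,Scleractinia
Pocillopora verrucosa,Scleractinia
Stylophora sp.,Scleractinia
Goniastrea retiformis,Scleractinia
Leptoria phrygia,Scleractinia
Favites sp.,Scleractinia
Cyphastrea sp.,Scleractinia
Leptastrea sp.,Scleractinia
Pavona sp.,Scleractinia
Psammocora sp.,Scleractinia
Galaxea sp.,Scleractinia
Acanthastrea sp.,Scleractinia
Lobophyllia sp.,Scleractinia
Halimeda opuntia,Green macroalgae
Halimeda minima,Green macroalgae
Caulerpa sp.,Green macroalgae
Chlorodesmis fastigiata,Green macroalgae
Dictyosphaeria sp.,Green macroalgae
Turf algae,Turf algae/Cyanobacteria/Bare substrate
Cyanobacteria mat,Turf algae/Cyanobacteria/Bare substrate
Bare substrate,Turf algae/Cyanobacteria/Bare substrate
Pavement,Turf algae/Cyanobacteria/Bare substrate
Sediment,Turf algae/Cyanobacteria/Bare substrate
Rubble,Turf algae/Cyanobacteria/Bare substrate
Porolithon onkodes,Corallinophycidae
Lithophyllum sp.,Corallinophycidae
Neogoniolithon sp.,Corallinophycidae
Crustose coralline algae indet.,Corallinophycidae
Encrusting sponge,Porifera
Massive sponge,Porifera
Cliona sp.,Porifera
Haliclona sp.,Porifera
Peyssonnelia sp. 1,Peyssonneliales
Peyssonnelia sp. 2,Peyssonneliales
Ramicrusta sp.,Peyssonneliales
Actinotrichia fragilis,Red macroalgae
Galaxaura sp.,Red macroalgae
Tricleocarpa sp.,Red macroalgae
Hypnea sp.,Red macroalgae
Laurencia sp.,Red macroalgae
Gelidiella sp.,Red macroalgae
Sinularia sp.,Octocorals/Hydrozoans
Sarcophyton sp.,Octocorals/Hydrozoans
Lobophytum sp.,Octocorals/Hydrozoans
Millepora sp.,Octocorals/Hydrozoans
Hydroid indet.,Octocorals/Hydrozoans
Lobophora sp.,Brown macroalgae
Padina sp.,Brown macroalgae
Dictyota sp.,Brown macroalgae
Turbinaria ornata,Brown macroalgae
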