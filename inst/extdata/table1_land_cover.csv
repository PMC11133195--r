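code,name,typology,reclass_group,habitat_category,functional_area,barrier_flag,area_ha
1,Rocky outcrops,forest_seminatural,Total others,rocky_sandy,grassland_paramo,FALSE,257.81
2,Natural sandy areas,forest_seminatural,Total others,rocky_sandy,grassland_paramo,FALSE,287.51
3,Glacial and snow zones,forest_seminatural,Total others,rocky_sandy,grassland_paramo,FALSE,66.12
4,Natural shrublands,forest_seminatural,Natural shrublands,shrubland,shrubland,FALSE,39627.44
5,Natural grasslands (Paramo),forest_seminatural,Natural grasslands (Paramo),grassland,grassland_paramo,FALSE,87665.07
6,Dense forest,forest_seminatural,Total primary forest,forest,forest,FALSE,117687.30
7,Riparian forest,forest_seminatural,Total primary forest,forest,forest,FALSE,2487.41
8,Fragmented forests,forest_seminatural,Total secondary forest,forest,forest,FALSE,29330.82
9,Secondary vegetation or in transition,forest_seminatural,Total secondary forest,shrubland,shrubland,FALSE,48542.91
10,Permanent woody crops,agricultural,Total permanent crops,heterogeneous_crops,crops,FALSE,3635.33
11,Sugarcane plantations,agricultural,Total permanent crops,sugarcane,sugarcane,FALSE,192742.20
12,Pasture and forest mosaic,agricultural,Total agricultural mosaics,heterogeneous_crops,agroforestry_mosaic,FALSE,75165.72
13,Cropland mosaic,agricultural,Total agricultural mosaics,heterogeneous_crops,crops,FALSE,1922.57
14,Cropland and forest mosaic,agricultural,Total agricultural mosaics,heterogeneous_crops,agroforestry_mosaic,FALSE,18478.08
15,"Cropland, forest, and pasture mosaic",agricultural,Total agricultural mosaics,heterogeneous_crops,agroforestry_mosaic,FALSE,152551.30
16,Cropland and pasture mosaic,agricultural,Total agricultural mosaics,heterogeneous_crops,crops,FALSE,64564.77
17,Wooded pastures,agricultural,Total pastures,pastures,pastures,FALSE,4673.74
18,Weeded pastures,agricultural,Total pastures,pastures,pastures,FALSE,41797.32
19,Clean pastures,agricultural,Total pastures,pastures,pastures,FALSE,84076.29
20,Timber plantations,agricultural,Timber plantations,forest,forest,FALSE,3238.40
21,Rivers and natural water bodies,water,Total water,water,water,FALSE,2569.59
22,Artificial water bodies,water,Total water,water,water,FALSE,1637.38
23,"Lagoons, lakes, and natural swamps",water,Total water,water,water,FALSE,527.56
24,Continuous urban fabric,built,Total urban and industrial areas,no_habitat,,TRUE,16228.67
25,Discontinuous urban fabric,built,Total urban and industrial areas,no_habitat,,TRUE,3447.70
26,Industrial or commercial areas,built,Total urban and industrial areas,no_habitat,,TRUE,4278.26
27,Nude and degraded soils,other,Nude soils,no_habitat,,TRUE,854.29
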