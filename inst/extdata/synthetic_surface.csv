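age_group,1950,1951,1952,1953,1954,1955,1956,1957,1958,1959,1960,1961,1962,1963,1964,1965,1966,1967,1968,1969,1970,1971,1972,1973,1974,1975,1976,1977,1978,1979,1980,1981,1982,1983,1984,1985,1986,1987,1988,1989,1990,1991,1992,1993,1994,1995,1996,1997,1998,1999,2000,2001
45-49,55.0536912235,54.8381259318,55.3528121117,57.0928059745,62.1561925374,54.8075622305,63.7476801207,61.0300945002, 56.826123236, 68.027869379,61.7274460742,62.5125934022,73.7517856835,57.8145863182,63.1391276988,62.7955001225,64.7129499438,55.8612294474,61.3032659536,60.2895383082,60.8946395884,66.8799359152,62.2014384613,64.7821617102,64.7425306512,67.9137499929,71.2157899335,59.8313787796,64.4412341559,62.8874792601,61.0908913515,67.6121674404,63.5348719602, 69.498280713,  68.57665917,63.3169080559,63.0320813213,67.0269282779,62.4808342875,70.7323574685,65.1733372362,60.9838888628,67.7141271787,63.8938363277, 63.342189416,74.9307018409,72.2272594048,70.4762677355,59.2828500986,66.6971584871,68.6713494538,59.0047695213
50-54,71.6225232819,73.2844096742,74.4069626969,76.2011399754, 78.303953378,86.9732429461,81.5083801451,78.5288724816,80.4336411581,84.1919767939, 80.843683568,85.1660371911, 88.859647727,80.4098471816,81.6894149044, 78.295772347,82.4332859001,80.4597036879,89.8150060816,85.5860316017,86.8101004542,90.3109594999,84.6939893764,90.4801399919,89.3392299651,86.8903198576,91.9418958562,81.2538124281,94.5479784043,83.5566700039,79.5199706467,85.8236028163,92.4023846522,88.8009710978,83.3487683651, 89.207590318,91.0281542564,84.3363424741,87.2762831998,90.8572464289,83.4264733319,86.9756351958,90.0198206796,83.8722058167,89.1924265685,91.0825204311,86.3293893567,89.6637036186,82.5181732013,88.6353894423,85.5240776173,84.7248001145
55-59,84.4658909012,90.0260558572,90.8215828827,96.4233944972,94.9778878356,108.380281794,102.401106663,98.7900616376,100.574437242,107.179838296,105.909864204,107.771113244, 112.78624282,111.538605763,105.307578491, 105.08738287,111.849506272,107.284342706,113.807742547,115.576391067,112.279288756,119.055929216,118.497314409,117.542051385,122.070784238, 111.74817731,116.541640613,114.768589049,127.842132335,116.421912129,114.272800106,118.991385649,117.484645963,120.228533485,118.272018964,123.411043217,119.743417544,120.186828801,119.616868437,127.313119237,112.315279933,122.034932716,110.958965626,123.045984314,113.027880896,122.462878088,117.141373334,114.844402318,113.060515861,125.216436371,112.816975058, 119.30585136
60-64, 102.83087954,103.929727069,120.573290325,  115.3435715,120.584598683,129.238243246,127.122244127,130.120052037,129.698180894,127.664819681, 136.11473583,131.729138815, 127.12783857,134.940283779,138.192482165,132.212882652, 143.17415558,138.954210294,144.394206004,138.883125948,141.756074711,141.316482998, 157.48926806,154.300418557,142.253650197,143.520932169,143.610979536,148.907667911, 147.38134274,145.214629931,145.504108956,144.043849783,158.572382688,144.126586421,162.250796261,149.474162724,150.176404043,149.480287062,143.426538898,156.714064663,144.526079571,147.747550028,161.236814464,160.900024112,161.155200696, 139.78559505,149.841941103,142.829521702,139.545151501,152.871995978,160.470618059,147.392895985
65-69,119.032099509,121.096813089,133.338926892,136.016643497, 137.67652265,142.606443022,149.528034879,149.926218456,148.484551524,155.396222311,167.843391993,150.392398416,166.908967173,159.913712988,161.953059687, 160.43439289,153.778688736,169.045911175, 173.61654357,163.807674774,176.287028511,159.673251646,188.763241466,178.885158598,173.295428214,178.658110669,174.165996588,172.758310015,170.147289986,169.766556376, 178.65932422,179.730796804,195.848961523,172.777269673,168.919414185,187.182329761,166.783384851,156.859816458,174.916763263,192.416140349,170.729977163,181.726231867,176.447000955,182.832780147,159.668736609,168.746029116,183.708082906,176.236513687,167.580498273,175.248299433,169.775878566,165.545690093
70-74,150.508461838, 158.40732891,150.279063774,166.912666383,160.609803104,175.367743564,161.718497971,178.548390291,163.917343403,174.054692589,175.452343536,173.878444972,194.769763606,173.138512819, 175.13865655,184.498191817,181.083935726,187.860286314,184.362164907,185.886748087,176.603415497,184.584237568,178.133297947,181.683379356,197.360182408,195.632753592,196.540878745,200.570409517,188.468914701,192.579130278,181.070999474, 192.71562963,190.332339134,194.848373486,195.858669848,204.354126781,180.986007939,200.173855482,202.494154306,202.022223527,188.465243586,202.862122199,190.229200677, 207.95895216,186.570472604,189.639175502,200.075609747,188.998301256,197.437080103, 194.36107433,194.878951719,199.612067089
75-79,166.273602266,177.850044683,181.345432363,188.908906371, 181.86252658,191.569449837,185.573349932,192.604757057,193.437322064,195.529525879,196.107793112,197.222094566,194.908722742,204.385212861, 197.24024252,193.247935974,194.523099653,207.348926714,183.110456374,201.860026529,192.665470475,199.142337027, 187.66095012,207.816808822,206.658302631,198.359375209,205.986172191,201.961404536, 209.38944885,207.865446278,200.787490786, 210.11731967, 221.99265335,213.838621239,226.777835602,218.840972632,194.272351378,210.890100861,202.355547987,189.748296873,196.312589132,226.977871661,207.370900441,217.892264104,199.191327123,222.887510888,208.472038562,199.840593379,207.104645778,205.199799488, 207.75939055,223.612068388
80-84,219.190642454,210.677839321, 205.20857077,196.532866566,221.696741797,  192.3554578,200.958887042,206.382667059,209.840185238,230.204923814,219.755547709,198.289864173,212.787393538,216.959725666, 214.21443184,219.949892084,220.412567697, 209.54640806,206.867783669,215.886138403,223.783698891,220.259410247,212.126719633,220.833179618,229.761620492,229.378359097,218.707944466,216.229985626,230.153049993,210.141961548,212.345677292,226.037662633,226.898735351,233.872581396,228.095040373,226.457161108,228.171429916,222.579221676,235.185005482,230.124387872, 237.99807421, 222.14226022,218.299973329,231.738804423, 228.73880567,237.876318843,234.341158455,220.453943735,223.702671904,215.201941301,227.298070304,225.255466472
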