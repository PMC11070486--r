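## Generated by tools/make_kappa_grid.R -- do not edit by hand.
## kappa(a/h, nu) grid for the bonded-layer flat-punch correction factor.

.kappa_ah_grid <- seq(0, 10, by = 0.05)
.kappa_nu_grid <- seq(0.30, 0.50, by = 0.05)

.kappa_grid <- matrix(c(
  1.00000000, 1.04576278, 1.09544069, 1.14905333, 1.20655824, 1.26785123, 1.33277090, 1.40110709, 1.47261200, 1.54701301, 1.62402541, 1.70336419, 1.78475376, 1.86793533, 1.95267177, 2.03875029, 2.12598320, 2.21420728, 2.30328220, 2.39308840, 2.48352463, 2.57450559, 2.66595953, 2.75782619, 2.85005488, 2.94260287, 3.03543400, 3.12851756, 3.22182732, 3.31534074, 3.40903833, 3.50290315, 3.59692038, 3.69107697, 3.78536137, 3.87976330, 3.97427356, 4.06888389, 4.16358685, 4.25837570, 4.35324429, 4.44818705, 4.54319888, 4.63827510, 4.73341142, 4.82860389, 4.92384888, 5.01914304, 5.11448325, 5.20986665, 5.30529059, 5.40075258, 5.49625033, 5.59178172, 5.68734475, 5.78293759, 5.87855851, 5.97420589, 6.06987824, 6.16557416, 6.26129234, 6.35703155, 6.45279064, 6.54856853, 6.64436423, 6.74017678, 6.83600530, 6.93184896, 7.02770698, 7.12357861, 7.21946318, 7.31536004, 7.41126856, 7.50718818, 7.60311836, 7.69905858, 7.79500837, 7.89096727, 7.98693485, 8.08291071, 8.17889446, 8.27488576, 8.37088425, 8.46688962, 8.56290155, 8.65891977, 8.75494400, 8.85097397, 8.94700945, 9.04305020, 9.13909601, 9.23514666, 9.33120195, 9.42726170, 9.52332572, 9.61939386, 9.71546594, 9.81154181, 9.90762133, 10.00370436, 10.09979076, 10.19588041, 10.29197318, 10.38806897, 10.48416766, 10.58026915, 10.67637334, 10.77248013, 10.86858944, 10.96470117, 11.06081525, 11.15693159, 11.25305012, 11.34917076, 11.44529345, 11.54141811, 11.63754470, 11.73367313, 11.82980336, 11.92593533, 12.02206898, 12.11820427, 12.21434113, 12.31047954, 12.40661943, 12.50276076, 12.59890350, 12.69504760, 12.79119302, 12.88733973, 12.98348768, 13.07963684, 13.17578719, 13.27193868, 13.36809128, 13.46424497, 13.56039971, 13.65655548, 13.75271225, 13.84887000, 13.94502869, 14.04118831, 14.13734882, 14.23351021, 14.32967246, 14.42583554, 14.52199944, 14.61816412, 14.71432958, 14.81049580, 14.90666275, 15.00283042, 15.09899879, 15.19516785, 15.29133758, 15.38750796, 15.48367898, 15.57985062, 15.67602288, 15.77219573, 15.86836916, 15.96454317, 16.06071773, 16.15689284, 16.25306848, 16.34924464, 16.44542132, 16.54159849, 16.63777615, 16.73395430, 16.83013291, 16.92631198, 17.02249150, 17.11867146, 17.21485186, 17.31103268, 17.40721391, 17.50339555, 17.59957758, 17.69576001, 17.79194282, 17.88812601, 17.98430956, 18.08049348, 18.17667774, 18.27286236, 18.36904732, 18.46523261, 18.56141823, 18.65760418, 18.75379044, 18.84997701, 18.94616388, 19.04235106, 19.13853853, 19.23472629, 19.33091433, 19.42710265, 19.52329124, 19.61948010, 19.71566923,
  1.00000000, 1.04790023, 1.10010202, 1.15665751, 1.21755156, 1.28270055, 1.35195601, 1.42511262, 1.50191976, 1.58209510, 1.66533866, 1.75134599, 1.83981944, 1.93047678, 2.02305724, 2.11732493, 2.21307021, 2.31010934, 2.40828310, 2.50745464, 2.60750697, 2.70834042, 2.80987015, 2.91202390, 3.01473992, 3.11796525, 3.22165424, 3.32576724, 3.43026967, 3.53513107, 3.64032449, 3.74582588, 3.85161366, 3.95766836, 4.06397229, 4.17050931, 4.27726464, 4.38422470, 4.49137694, 4.59870976, 4.70621238, 4.81387480, 4.92168771, 5.02964239, 5.13773074, 5.24594514, 5.35427849, 5.46272411, 5.57127576, 5.67992756, 5.78867399, 5.89750989, 6.00643037, 6.11543085, 6.22450702, 6.33365483, 6.44287043, 6.55215025, 6.66149087, 6.77088910, 6.88034192, 6.98984649, 7.09940012, 7.20900028, 7.31864458, 7.42833076, 7.53805669, 7.64782036, 7.75761986, 7.86745341, 7.97731930, 8.08721593, 8.19714178, 8.30709541, 8.41707548, 8.52708070, 8.63710986, 8.74716180, 8.85723544, 8.96732975, 9.07744376, 9.18757653, 9.29772721, 9.40789495, 9.51807898, 9.62827854, 9.73849294, 9.84872150, 9.95896359, 10.06921860, 10.17948597, 10.28976514, 10.40005562, 10.51035689, 10.62066851, 10.73099003, 10.84132103, 10.95166111, 11.06200988, 11.17236700, 11.28273210, 11.39310488, 11.50348502, 11.61387221, 11.72426618, 11.83466666, 11.94507340, 12.05548614, 12.16590466, 12.27632873, 12.38675814, 12.49719269, 12.60763218, 12.71807644, 12.82852529, 12.93897855, 13.04943606, 13.15989768, 13.27036326, 13.38083265, 13.49130572, 13.60178234, 13.71226239, 13.82274575, 13.93323231, 14.04372196, 14.15421459, 14.26471011, 14.37520843, 14.48570944, 14.59621306, 14.70671921, 14.81722780, 14.92773877, 15.03825203, 15.14876751, 15.25928514, 15.36980486, 15.48032660, 15.59085031, 15.70137592, 15.81190337, 15.92243262, 16.03296361, 16.14349628, 16.25403060, 16.36456650, 16.47510395, 16.58564291, 16.69618333, 16.80672517, 16.91726839, 17.02781295, 17.13835882, 17.24890596, 17.35945434, 17.47000392, 17.58055467, 17.69110657, 17.80165958, 17.91221367, 18.02276881, 18.13332498, 18.24388216, 18.35444031, 18.46499942, 18.57555945, 18.68612039, 18.79668221, 18.90724489, 19.01780842, 19.12837276, 19.23893791, 19.34950384, 19.46007053, 19.57063797, 19.68120614, 19.79177502, 19.90234459, 20.01291485, 20.12348576, 20.23405733, 20.34462953, 20.45520235, 20.56577578, 20.67634980, 20.78692440, 20.89749957, 21.00807530, 21.11865157, 21.22922836, 21.33980568, 21.45038351, 21.56096184, 21.67154066, 21.78211995, 21.89269972, 22.00327994, 22.11386061, 22.22444172, 22.33502326,
  1.00000000, 1.05071027, 1.10626243, 1.16676479, 1.23225336, 1.30268842, 1.37795620, 1.45787590, 1.54221097, 1.63068328, 1.72298838, 1.81881028, 1.91783449, 2.01975832, 2.12429840, 2.23119532, 2.34021584, 2.45115324, 2.56382617, 2.67807673, 2.79376800, 2.91078147, 3.02901440, 3.14837751, 3.26879276, 3.39019154, 3.51251307, 3.63570308, 3.75971273, 3.88449768, 4.01001741, 4.13623465, 4.26311484, 4.39062582, 4.51873753, 4.64742170, 4.77665173, 4.90640246, 5.03665010, 5.16737206, 5.29854688, 5.43015416, 5.56217448, 5.69458933, 5.82738107, 5.96053287, 6.09402867, 6.22785317, 6.36199172, 6.49643037, 6.63115579, 6.76615525, 6.90141659, 7.03692819, 7.17267898, 7.30865837, 7.44485624, 7.58126294, 7.71786925, 7.85466637, 7.99164589, 8.12879979, 8.26612040, 8.40360041, 8.54123282, 8.67901099, 8.81692853, 8.95497937, 9.09315772, 9.23145804, 9.36987503, 9.50840366, 9.64703911, 9.78577678, 9.92461229, 10.06354145, 10.20256025, 10.34166489, 10.48085172, 10.62011726, 10.75945819, 10.89887134, 11.03835369, 11.17790235, 11.31751455, 11.45718767, 11.59691918, 11.73670669, 11.87654790, 12.01644061, 12.15638274, 12.29637229, 12.43640734, 12.57648607, 12.71660673, 12.85676766, 12.99696726, 13.13720401, 13.27747646, 13.41778320, 13.55812292, 13.69849434, 13.83889623, 13.97932744, 14.11978685, 14.26027340, 14.40078606, 14.54132385, 14.68188586, 14.82247117, 14.96307893, 15.10370832, 15.24435856, 15.38502889, 15.52571859, 15.66642697, 15.80715336, 15.94789714, 16.08865769, 16.22943443, 16.37022679, 16.51103425, 16.65185628, 16.79269240, 16.93354212, 17.07440499, 17.21528057, 17.35616844, 17.49706820, 17.63797946, 17.77890185, 17.91983501, 18.06077859, 18.20173227, 18.34269572, 18.48366864, 18.62465073, 18.76564171, 18.90664131, 19.04764927, 19.18866533, 19.32968924, 19.47072078, 19.61175972, 19.75280583, 19.89385892, 20.03491877, 20.17598519, 20.31705800, 20.45813701, 20.59922204, 20.74031293, 20.88140952, 21.02251164, 21.16361915, 21.30473190, 21.44584974, 21.58697254, 21.72810016, 21.86923249, 22.01036939, 22.15151074, 22.29265643, 22.43380634, 22.57496038, 22.71611842, 22.85728038, 22.99844615, 23.13961564, 23.28078875, 23.42196540, 23.56314550, 23.70432896, 23.84551571, 23.98670566, 24.12789874, 24.26909488, 24.41029399, 24.55149602, 24.69270090, 24.83390856, 24.97511893, 25.11633195, 25.25754757, 25.39876572, 25.53998635, 25.68120940, 25.82243483, 25.96366257, 26.10489258, 26.24612480, 26.38735920, 26.52859571, 26.66983431, 26.81107494, 26.95231756, 27.09356213, 27.23480861, 27.37605696, 27.51730714, 27.65855911,
  1.00000000, 1.05446501, 1.11455062, 1.18046453, 1.25233992, 1.33022835, 1.41409843, 1.50384041, 1.59927614, 1.70017302, 1.80625994, 1.91724353, 2.03282296, 2.15270221, 2.27659941, 2.40425306, 2.53542549, 2.66990405, 2.80750065, 2.94805015, 3.09140807, 3.23744802, 3.38605910, 3.53714344, 3.69061393, 3.84639228, 4.00440739, 4.16459394, 4.32689127, 4.49124247, 4.65759366, 4.82589342, 4.99609236, 5.16814277, 5.34199838, 5.51761412, 5.69494601, 5.87395105, 6.05458713, 6.23681295, 6.42058802, 6.60587259, 6.79262766, 6.98081495, 7.17039688, 7.36133660, 7.55359795, 7.74714547, 7.94194439, 8.13796067, 8.33516095, 8.53351255, 8.73298352, 8.93354258, 9.13515914, 9.33780333, 9.54144592, 9.74605840, 9.95161291, 10.15808227, 10.36543997, 10.57366013, 10.78271757, 10.99258769, 11.20324657, 11.41467089, 11.62683796, 11.83972568, 12.05331255, 12.26757766, 12.48250068, 12.69806182, 12.91424188, 13.13102215, 13.34838451, 13.56631132, 13.78478545, 14.00379028, 14.22330968, 14.44332798, 14.66382998, 14.88480092, 15.10622651, 15.32809286, 15.55038651, 15.77309441, 15.99620390, 16.21970273, 16.44357899, 16.66782116, 16.89241808, 17.11735892, 17.34263319, 17.56823074, 17.79414172, 18.02035661, 18.24686616, 18.47366144, 18.70073379, 18.92807481, 19.15567639, 19.38353067, 19.61163002, 19.83996708, 20.06853471, 20.29732600, 20.52633426, 20.75555301, 20.98497599, 21.21459712, 21.44441053, 21.67441054, 21.90459164, 22.13494849, 22.36547594, 22.59616900, 22.82702284, 23.05803276, 23.28919425, 23.52050292, 23.75195452, 23.98354494, 24.21527021, 24.44712646, 24.67910998, 24.91121716, 25.14344448, 25.37578858, 25.60824616, 25.84081407, 26.07348921, 26.30626862, 26.53914942, 26.77212880, 27.00520407, 27.23837260, 27.47163186, 27.70497938, 27.93841279, 28.17192978, 28.40552810, 28.63920560, 28.87296017, 29.10678977, 29.34069244, 29.57466626, 29.80870938, 30.04282000, 30.27699638, 30.51123682, 30.74553970, 30.97990341, 31.21432643, 31.44880725, 31.68334443, 31.91793655, 32.15258226, 32.38728024, 32.62202919, 32.85682786, 33.09167506, 33.32656960, 33.56151034, 33.79649619, 34.03152605, 34.26659889, 34.50171369, 34.73686948, 34.97206528, 35.20730018, 35.44257327, 35.67788368, 35.91323054, 36.14861304, 36.38403037, 36.61948174, 36.85496640, 37.09048360, 37.32603262, 37.56161277, 37.79722337, 38.03286374, 38.26853326, 38.50423129, 38.73995722, 38.97571045, 39.21149042, 39.44729656, 39.68312832, 39.91898517, 40.15486659, 40.39077207, 40.62670113, 40.86265328, 41.09862805, 41.33462500, 41.57064367, 41.80668364, 42.04274448, 42.27882579, 42.51492716,
  1.00000000, 1.05959858, 1.12598727, 1.19955809, 1.28063661, 1.36947016, 1.46622193, 1.57097158, 1.68372229, 1.80441307, 1.93293437, 2.06914506, 2.21288873, 2.36400791, 2.52235539, 2.68780233, 2.86024323, 3.03959836, 3.22581410, 3.41886183, 3.61873585, 3.82545089, 4.03903933, 4.25954861, 4.48703864, 4.72157970, 4.96325043, 5.21213624, 5.46832796, 5.73192073, 6.00301308, 6.28170626, 6.56810361, 6.86231015, 7.16443220, 7.47457712, 7.79285308, 8.11936888, 8.45423385, 8.79755769, 9.14945045, 9.51002241, 9.87938406, 10.25764605, 10.64491914, 11.04131420, 11.44694219, 11.86191410, 12.28634099, 12.72033395, 13.16400408, 13.61746251, 14.08082038, 14.55418883, 15.03767899, 15.53140202, 16.03546903, 16.54999117, 17.07507954, 17.61084524, 18.15739938, 18.71485302, 19.28331724, 19.86290309, 20.45372160, 21.05588379, 21.66950068, 22.29468325, 22.93154249, 23.58018935, 24.24073479, 24.91328973, 25.59796511, 26.29487183, 27.00412078, 27.72582284, 28.46008889, 29.20702978, 29.96675635, 30.73937943, 31.52500986, 32.32375843, 33.13573595, 33.96105322, 34.79982099, 35.65215006, 36.51815118, 37.39793509, 38.29161255, 39.19929428, 40.12109102, 41.05711348, 42.00747236, 42.97227838, 43.95164223, 44.94567460, 45.95448617, 46.97818761, 48.01688960, 49.07070279, 50.13973784, 51.22410541, 52.32391614, 53.43928066, 54.57030963, 55.71711365, 56.87980337, 58.05848939, 59.25328234, 60.46429283, 61.69163146, 62.93540884, 64.19573556, 65.47272223, 66.76647942, 68.07711774, 69.40474775, 70.74948005, 72.11142521, 73.49069381, 74.88739640, 76.30164357, 77.73354588, 79.18321389, 80.65075815, 82.13628923, 83.63991768, 85.16175404, 86.70190888, 88.26049273, 89.83761613, 91.43338964, 93.04792378, 94.68132910, 96.33371614, 98.00519541, 99.69587747, 101.40587283, 103.13529202, 104.88424557, 106.65284401, 108.44119785, 110.24941762, 112.07761383, 113.92589700, 115.79437765, 117.68316629, 119.59237344, 121.52210961, 123.47248530, 125.44361103, 127.43559730, 129.44855462, 131.48259349, 133.53782442, 135.61435792, 137.71230447, 139.83177459, 141.97287876, 144.13572750, 146.32043130, 148.52710064, 150.75584604, 153.00677798, 155.28000695, 157.57564345, 159.89379797, 162.23458100, 164.59810303, 166.98447454, 169.39380604, 171.82620799, 174.28179090, 176.76066524, 179.26294150, 181.78873017, 184.33814173, 186.91128666, 189.50827544, 192.12921855, 194.77422649, 197.44340972, 200.13687872, 202.85474398, 205.59711597, 208.36410518, 211.15582207, 213.97237713, 216.81388083, 219.68044365, 222.57217606, 225.48918854, 228.43159156, 231.39949560, 234.39301112, 237.41224861, 240.45731853, 243.52833135, 246.62539756, 249.74862761, 252.89813198
), nrow = 201, ncol = 5)
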