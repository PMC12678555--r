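sample_id,taxon,period_true,age,d15N,d13C,elevation,material,cn_atomic,pctC,pctN,lat,lon
iso0001,brown_bear,Meghalayan,1.5952294580565534,4.167143734212279,-21.38047100101238,699.1532624703048,bone,3.208823389839381,31.542969663860276,15.909741879906505,57.275257458910346,-3.9028680289629847
iso0002,brown_bear,Meghalayan,2.5736382131390667,4.043050118329594,-21.694706978920514,692.0672726837598,bone,3.394097917014733,36.52339112246409,15.358306686393917,40.20126360654831,16.470975076546893
iso0003,brown_bear,Northgrippian,7.857752746733025,3.135163878592396,-21.225770985659267,261.7869779586256,bone,3.0303602857748047,40.80894410144538,13.295707936398685,50.051600474864244,16.267845693742856
iso0004,brown_bear,Northgrippian,6.63493992867542,3.0169351921337744,-19.48352939557046,152.69592270206815,bone,3.4738634700188413,32.13441443396732,15.724547431338578,45.70824676193297,3.4730040666181594
iso0005,brown_bear,Greenlandian,10.509434573204725,8.176026136028971,-20.206414692321278,236.96603497764548,tooth,3.204737476306036,32.75774286012165,11.386970692314208,37.84058796800673,19.553273015655577
iso0006,brown_bear,Greenlandian,11.076319109688132,7.286340585679463,-21.152410633064765,1322.1602419840558,tooth,3.0052335559157655,42.64093978330493,11.434599733911455,41.89736827276647,24.05067343893461
iso0007,brown_bear,GS-1,12.287056739467156,5.1720810269591135,-21.768473602939718,373.10457867188205,tooth,3.091914245393127,41.198520062025636,13.708107239566743,48.716056460514665,13.688253891421482
iso0008,brown_bear,GS-1,12.514367795693756,5.094383725663581,-21.62591091307165,94.36754393809265,bone,3.43182205571793,40.02426974591799,12.233428361359984,56.992376228794456,23.75094282673672
iso0009,brown_bear,GI-1,14.48716535954137,6.363909783024451,-21.235700359100477,240.2389124212846,tooth,3.1193630134221166,39.020485889632255,12.415440053213388,44.73820475488901,-2.3448358308523893
iso0010,brown_bear,GI-1,13.63975886371831,3.185868486521687,-22.026420900306782,451.65841963837056,bone,3.481179468217306,37.725445908727124,15.281479247380048,42.91774273663759,-2.285301891155541
iso0011,brown_bear,GS-2 to GI-2,20.571463212755518,5.70409125103055,-21.26573894389719,361.33984974255253,bone,3.457841769210063,36.426322631305084,10.350870931521058,45.53164687938988,23.445174950407818
iso0012,brown_bear,GS-2 to GI-2,15.05974230206875,7.084525733389099,-20.84838862928558,526.1761206027975,bone,3.309175613685511,38.131205508252606,11.565141142345965,40.74587368033826,-3.0373983099125326
iso0013,brown_bear,GS-3 to GI-8,26.60464022617029,4.69359160691164,-21.620326487077463,682.0221141526737,bone,3.202199590508826,43.02160210325383,15.291865355800837,58.80400750413537,13.484241830650717
iso0014,brown_bear,GS-3 to GI-8,32.13638020943685,6.220330180923224,-20.209809749404027,514.1916956088132,bone,3.235788138816133,43.885619337670505,14.045121055096388,48.39467746205628,4.116917030420154
iso0015,brown_bear,GS-9 to GI-14,51.68936896211046,7.846056769606619,-21.262197489402467,264.43665526922564,tooth,3.032464149990119,30.81943663652055,11.78645069571212,37.725698333233595,20.415648680878803
iso0016,brown_bear,GS-9 to GI-14,45.225903242316825,8.20977515239158,-22.572144159145488,801.3951056393502,tooth,3.1129432164598256,40.054230593377724,10.604329493828118,57.13057365082204,22.847629616735503
iso0017,red_deer,Meghalayan,1.4867416306584238,2.440132612735625,-21.536242590451263,1293.6780111978508,tooth,3.0174374020425603,39.25852904445492,15.004325855057687,52.73697038926184,29.136282788123935
iso0018,red_deer,Meghalayan,3.5989187638088374,4.184597675977914,-20.46408294356349,84.45697167801845,tooth,3.1691956418799236,34.29428023053333,11.88562468253076,51.395096495747566,7.174678043927997
iso0019,red_deer,Meghalayan,3.5858061691124723,0.34173411056101477,-22.828626633876084,1041.8330513737096,bone,3.45753188082017,41.066961045144126,12.955399286933243,51.45414995960891,-4.343213580781594
iso0020,red_deer,Northgrippian,7.786954729666126,1.975840788367231,-20.214408837129692,395.25827575111583,tooth,3.1714044008404016,38.00647310446948,11.253258091397583,50.037602243945,20.998562537832186
iso0021,red_deer,Northgrippian,5.432478216913677,4.299686695991488,-23.10224732350156,364.6416125364351,bone,3.4332416573306546,44.45764997857623,11.852720996364951,54.259767008945346,11.969410138903186
iso0022,red_deer,Northgrippian,5.653202173681844,2.0062307928985197,-21.0422049297154,293.16459562901895,bone,3.2275540254777297,41.61887313122861,15.828054701443762,44.9450254663825,26.645822536898777
iso0023,red_deer,Greenlandian,10.672756653317622,4.0682510617369365,-20.530097808379374,150.95680124681482,tooth,3.0960116593632847,37.17684575705789,13.865441323257983,57.3867434989661,6.139981886604801
iso0024,red_deer,Greenlandian,8.488759610183921,7.692079067360248,-20.039617642799097,169.07668631234685,tooth,3.4753106320276856,30.419888579053804,13.577581267803907,51.03016673773527,-2.7414713934995234
iso0025,red_deer,Greenlandian,9.387594030295187,3.604416953395263,-21.005141288383037,581.4819559254855,tooth,3.160862768883817,38.211892020190135,11.931624254211783,43.269717967137694,24.639524003723636
iso0026,red_deer,GS-1,12.440665728880106,1.953365786364804,-21.70459646368007,1063.5728190709472,bone,3.077455862890929,36.54194994131103,13.50961934402585,52.58898795582354,-5.337252323515713
iso0027,red_deer,GS-1,12.276204861293127,5.262555364447168,-21.71721816157401,252.08596465904776,tooth,3.0623710443032905,36.96024940232746,11.624668116681278,42.788457591086626,23.05917277559638
iso0028,red_deer,GS-1,12.084781971689688,5.4308756568106595,-20.11534950102308,467.7806509255134,tooth,3.4873629042413086,32.4794712185394,11.380581522360444,55.44955358840525,7.669702947372571
iso0029,red_deer,GI-1,13.029870238073988,2.2749856221466005,-21.179051594380198,617.255238259893,tooth,3.22989259660244,31.304102519061416,11.51859396416694,52.47179872356355,4.790636963211
iso0030,red_deer,GI-1,14.0208029426837,2.0870369402699316,-19.097638178321073,333.503194518433,bone,3.350792559213005,44.89416024181992,10.297230613883585,54.8862564638257,5.291216353420168
iso0031,red_deer,GS-2 to GI-2,18.556426192039346,4.580447674455097,-22.532902002890598,222.69276684130725,bone,3.156056395964697,37.7820738509763,15.419401361607015,59.73787849768996,27.6263976234477
iso0032,red_deer,GS-2 to GI-2,21.30078140632063,5.865386692338068,-21.52111731755252,145.6431604462607,bone,3.0186849824385718,40.18520123558119,10.153160190675408,43.26930299028754,17.81669568736106
iso0033,red_deer,GS-3 to GI-8,37.66587329375535,3.2390395419443463,-19.944661408956364,335.3390835356781,bone,3.102469351491891,43.32082785665989,13.521751940716058,48.717419005930424,-8.369741244474426
iso0034,red_deer,GS-3 to GI-8,24.51385174420432,2.1154273274716786,-21.291920756917346,596.6993712653439,bone,3.28469133132603,37.9457113717217,13.994410855229944,48.23622958548367,-7.139310587430373
iso0035,red_deer,GS-9 to GI-14,53.67568735813759,2.441147749859052,-21.219050378933474,960.626383195874,bone,3.43933701061178,42.811499662930146,15.243699477054179,42.76348007284105,29.11795949516818
iso0036,red_deer,GS-9 to GI-14,51.17399419531103,3.654451935951792,-20.831934616115344,162.3530153485697,bone,3.406426343950443,35.518439216539264,10.908029028680176,52.00092378817499,13.726849729428068
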