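index,phrase
1,maman trop occupée
1,mother too busy
2,l'enfant était malade
2,child was sick
3,centre de vaccination trop loin
3,site too far away
4,peur des effets secondaires
4,fear of side effects
5,pas de vaccin disponible
5,vaccine out of stock
6,l'infirmier était absent
6,health worker absent
7,ne savait pas où aller
7,did not know where to go
8,ne savait pas que c'était nécessaire
8,did not know it was needed
9,mauvaise heure de la séance
9,session at the wrong time
10,attente trop longue
10,waiting line too long
11,la famille a refusé
11,family refused
12,croyances religieuses
12,religious beliefs
13,maman souffrante après l'accouchement
13,mother unwell after delivery
14,carnet de vaccination perdu
14,vaccination card lost
15,manque d'argent pour les frais
15,could not pay the fees
16,insécurité dans la zone
16,insecurity in the area
17,interruption à cause de l'épidémie
17,services stopped by the epidemic
18,enfant encore trop petit
18,child still too young
19,méfiance envers les services de santé
19,distrust of health services
20,pas de moyen de transport
20,no transport available
21,le papa a refusé
21,father refused
22,autres obligations familiales
22,other family duties
23,voyage de la famille
23,family was travelling
23,en déplacement
24,négligence
24,simple negligence
25,calendrier vaccinal en cours
25,vaccine schedule in progress
26,grève des infirmiers
26,health workers on strike
27,travaux aux champs
27,working in the field
28,rumeurs sur les vaccins
28,rumors about the vaccines
29,maman absente du village
29,mother away from home
30,enfant né à la maison
30,child born at home
31,rendez-vous oublié
31,forgot the appointment
32,pas informé de la séance
32,not informed of the session
33,forte pluie ce jour-là
33,heavy rain that day
34,rivière infranchissable
34,river impassable
35,centre de santé fermé
35,health facility closed
36,vaccination reportée par le personnel
36,vaccination postponed by staff
37,gardien malade
37,caregiver was ill
38,jumeaux à la maison
38,twins to care for
39,déménagement vers une autre zone
39,moved to another area
40,attend la campagne de vaccination
40,waiting for the campaign
41,l'enfant a pleuré et refusé
41,child cried and refused
42,conflit dans la famille
42,conflict in the family
43,aucune raison donnée
43,no reason given
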